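#' Build a suffix-array index
#'
#' Precomputes the suffix array, inverse suffix array and LCP heights of
#' the encoded sequence (breaks become sentinels smaller than any base), as
#' well as the per-position occurrence count of each k-mer. Construction is
#' by prefix doubling; occurrence queries then run in output-linear time by
#' scanning outward from a position's suffix-array rank while the LCP stays
#' at least k.
#'
#' @inheritParams selectMinimizers
#' @param k k-mer length the index should answer queries for.
#' @return A \linkS4class{SuffixIndex}.
#' @export
buildSuffixIndex <- function(x, k) {
  .checkWK(2L, k)
  codes <- .seqCodes(x)
  sar <- cpp_suffix_array(codes)
  valid <- cpp_valid_starts(codes, as.integer(k))
  freq <- cpp_kmer_freq(sar$sa, sar$lcp, valid, as.integer(k))
  new("SuffixIndex", sa = sar$sa, isa = sar$isa, lcp = sar$lcp,
      freq = freq, valid = valid, k = as.integer(k),
      n = length(codes))
}

#' @rdname occurrences
setMethod("occurrences", "SuffixIndex", function(x, t) {
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > x@n)
    stop("position out of range")
  if (!x@valid[t])
    stop("no break-free k-mer starts at position ", t)
  cpp_sa_occurrences(x@sa, x@isa, x@lcp, t - 1L, x@k) + 1L
})

#' @rdname frequencyThreshold
setMethod("frequencyThreshold", "SuffixIndex", function(x, percentile) {
  if (length(percentile) != 1L || is.na(percentile) || percentile <= 0 ||
      percentile > 1)
    stop("percentile must lie in (0, 1]")
  v <- sort(x@freq[x@valid])
  if (length(v) == 0) stop("index holds no valid k-mer positions")
  uq <- unique(v)
  cumfrac <- cumsum(tabulate(match(v, uq), nbins = length(uq))) / length(v)
  uq[which(cumfrac >= percentile - 1e-12)[1]]
})

#' @describeIn SuffixIndex-class k-mer length of the index.
#' @param x a \linkS4class{SuffixIndex}.
#' @export
setMethod("kmerSize", "SuffixIndex", function(x) x@k)

#' @describeIn SuffixIndex-class number of valid k-mer positions.
#' @export
setMethod("nKmers", "SuffixIndex", function(x) sum(x@valid))

setMethod("show", "SuffixIndex", function(object) {
  cat("SuffixIndex: n =", object@n, ", k =", object@k, "\n")
  cat("  valid k-mer positions:", sum(object@valid), "\n")
  if (any(object@valid))
    cat("  max k-mer frequency:", max(object@freq), "\n")
})
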