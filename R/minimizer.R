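#' Apply a minimizer scheme to a sequence
#'
#' Runs the minimizer (w, k, O) over every window of \code{w} consecutive
#' k-mers: each window selects the position of its smallest k-mer under the
#' order \code{order}, preferring the leftmost position on ties. Windows
#' never span breaks (non-ACGT characters or record boundaries); each
#' break-free fragment is processed independently and results are
#' aggregated.
#'
#' A context (w + 1 consecutive k-mers, i.e. two overlapping windows) is
#' \emph{charged} when its two windows select different positions; on a
#' break-free sequence the number of selected positions is exactly the
#' number of charged contexts plus one.
#'
#' @param x sequence input (character, DNAStringSet or FASTA path).
#' @param w window size in k-mers (>= 2).
#' @param k k-mer length (1..31).
#' @param order a \linkS4class{KmerOrder}; the default is a random
#'   minimizer order with seed 1.
#' @return A \linkS4class{MinimizerSelection}.
#' @examples
#' sel <- selectMinimizers("ACGTACGGTCAGCT", w = 3, k = 2)
#' selectedPositions(sel)
#' densityFactor(sel)
#' @seealso \code{\link{densityFactor}}, \code{\link{energyProfile}}
#' @export
selectMinimizers <- function(x, w, k, order = KmerOrder(seed = 1L)) {
  .checkWK(w, k)
  stopifnot(is(order, "KmerOrder"))
  flat <- .flattenLayers(order@layers, k)
  codes <- .seqCodes(x)
  res <- cpp_select_positions(codes, as.integer(w), as.integer(k),
                              flat$kmers, flat$ids, order@seed)
  if (res$n_windows == 0)
    stop("sequence too short: no fragment holds a full window of ",
         w, " k-mers (w + k - 1 = ", w + k - 1, " bases)")
  new("MinimizerSelection", positions = res$positions + 1L,
      nCharged = res$n_charged, nWindows = res$n_windows,
      nContexts = res$n_contexts, nKmers = res$n_kmers,
      nFragments = res$n_fragments,
      nFragmentsWithWindows = res$n_fragments_with_windows,
      w = as.integer(w), k = as.integer(k))
}

.flattenLayers <- function(layers, k) {
  if (length(layers) == 0)
    return(list(kmers = character(0), ids = integer(0)))
  km <- unlist(layers, use.names = FALSE)
  if (length(km) > 0 && any(nchar(km) != k))
    stop("layer k-mers must all have length k = ", k)
  list(kmers = km, ids = rep.int(seq_along(layers), lengths(layers)))
}

#' Select the minimizer position within one window
#'
#' @param kmers character vector of exactly \code{w} k-mers (the window, in
#'   order).
#' @param order a \linkS4class{KmerOrder}.
#' @param w optional window size to enforce (defaults to
#'   \code{length(kmers)}).
#' @return 1-based index of the selected k-mer within the window (leftmost
#'   minimum).
#' @export
selectInWindow <- function(kmers, order = KmerOrder(seed = 1L), w = NULL) {
  if (!is.null(w) && length(kmers) != w)
    stop("window must contain exactly w = ", w, " k-mers, got ",
         length(kmers))
  if (length(kmers) < 1) stop("empty window")
  k <- nchar(kmers[1])
  flat <- .flattenLayers(order@layers, k)
  r <- cpp_rank_kmers(as.character(kmers), flat$kmers, flat$ids,
                      as.integer(k), order@seed)
  which.min(r)
}

#' @describeIn MinimizerSelection-class selected positions (1-based).
#' @param x a \linkS4class{MinimizerSelection}.
#' @export
setMethod("selectedPositions", "MinimizerSelection",
          function(x) x@positions)

#' @describeIn MinimizerSelection-class selected positions over k-mers of
#'   the sequence.
#' @export
setMethod("specificDensity", "MinimizerSelection", function(x) {
  length(x@positions) / x@nKmers
})

#' @describeIn MinimizerSelection-class density times (w + 1); about 2 for
#'   a random minimizer, about 1 for a perfect one.
#' @export
setMethod("densityFactor", "MinimizerSelection", function(x) {
  specificDensity(x) * (x@w + 1)
})

#' @describeIn MinimizerSelection-class number of charged contexts.
#' @export
setMethod("nCharged", "MinimizerSelection", function(x) x@nCharged)

#' @describeIn MinimizerSelection-class number of contexts.
#' @export
setMethod("nContexts", "MinimizerSelection", function(x) x@nContexts)

#' @describeIn MinimizerSelection-class number of k-mers in the sequence.
#' @export
setMethod("nKmers", "MinimizerSelection", function(x) x@nKmers)

#' @describeIn MinimizerSelection-class window size.
#' @export
setMethod("windowSize", "MinimizerSelection", function(x) x@w)

#' @describeIn MinimizerSelection-class k-mer length.
#' @export
setMethod("kmerSize", "MinimizerSelection", function(x) x@k)

setMethod("show", "MinimizerSelection", function(object) {
  cat("MinimizerSelection (w =", object@w, ", k =", object@k, ")\n")
  cat("  ", length(object@positions), "selected positions over",
      format(object@nKmers, big.mark = ","), "k-mers\n")
  cat("  charged contexts:", object@nCharged,
      " windows:", object@nWindows, "\n")
  cat(sprintf("  specific density: %.6g   density factor: %.4f\n",
              specificDensity(object), densityFactor(object)))
})

#' @describeIn KmerOrder-class the layer list.
#' @param x a \linkS4class{KmerOrder}.
#' @export
setMethod("layers", "KmerOrder", function(x) x@layers)

setMethod("show", "KmerOrder", function(object) {
  if (length(object@layers) == 0) {
    cat("KmerOrder: random order (seed", object@seed, ")\n")
  } else {
    cat("KmerOrder: compatible with", length(object@layers),
        "layer(s) of sizes", paste(lengths(object@layers), collapse = ", "),
        "(seed", object@seed, ")\n")
  }
})
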