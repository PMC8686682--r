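#' Total k-mer order for minimizer selection
#'
#' A strict total order over k-mers given by (layer rank, seeded
#' pseudo-random rank). Two k-mers compare first by the smallest layer
#' containing them (a k-mer outside every layer compares larger than any
#' layer member, making the order \emph{compatible} with the layered set),
#' then by a seeded 64-bit avalanche hash of the packed k-mer, with hash
#' collisions broken by lexicographic rank. The order is deterministic
#' given (layers, seed); with no layers it is the usual random minimizer
#' order.
#'
#' @slot layers list of character vectors of k-mers; earlier layers compare
#'   smaller. May be empty.
#' @slot seed single integer seeding the hash.
#' @export
setClass("KmerOrder",
         representation(layers = "list", seed = "integer"))

setValidity("KmerOrder", function(object) {
  msg <- .checkLayers(object@layers)
  if (!is.null(msg)) return(msg)
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single non-missing integer")
  TRUE
})

#' @param layers list of character vectors of k-mers, highest priority
#'   first.
#' @param seed integer hash seed.
#' @rdname KmerOrder-class
#' @export
KmerOrder <- function(layers = list(), seed = 1L) {
  if (is.character(layers)) layers <- list(layers)
  new("KmerOrder", layers = lapply(layers, as.character),
      seed = as.integer(seed))
}

#' Layered polar set
#'
#' An ordered list of pairwise-disjoint k-mer sets \code{A1..Am} with
#' slackness \code{s}. Validity on a given sequence (every member
#' occurrence either at least \code{ceiling((1 - s) * w)} bases from all
#' other member occurrences, or covered by two flanking earlier-layer
#' occurrences at most \code{w} apart) is checked against a sequence by
#' \code{\link{validateLayered}}; with a single layer this degenerates to a
#' plain polar set. \code{metadata} carries construction details such as
#' the per-round build log.
#'
#' @slot layers list of character vectors, highest priority first.
#' @slot w integer window size (in k-mers).
#' @slot k integer k-mer length.
#' @slot s numeric slackness in [0, 1/2).
#' @slot metadata list of construction details.
#' @export
setClass("LayeredPolarSet",
         representation(layers = "list", w = "integer", k = "integer",
                        s = "numeric", metadata = "list"))

setValidity("LayeredPolarSet", function(object) {
  msg <- .checkLayers(object@layers)
  if (!is.null(msg)) return(msg)
  if (length(object@w) != 1L || object@w < 2L)
    return("w must be a single integer >= 2")
  if (length(object@k) != 1L || object@k < 1L || object@k > 31L)
    return("k must be a single integer in [1, 31]")
  widths <- unique(nchar(unlist(object@layers)))
  if (length(widths) > 0 && !identical(widths, as.integer(object@k)) &&
      !identical(as.integer(widths), as.integer(object@k)))
    return("all member k-mers must have length k")
  if (length(object@s) != 1L || object@s < 0 || object@s >= 0.5)
    return("slackness s must lie in [0, 1/2)")
  TRUE
})

#' @param layers list of character vectors of k-mers (layer 1 first).
#' @param w,k window size and k-mer length.
#' @param s slackness in [0, 1/2).
#' @param metadata optional list of construction details.
#' @rdname LayeredPolarSet-class
#' @export
LayeredPolarSet <- function(layers, w, k, s = 0.4, metadata = list()) {
  if (is.character(layers)) layers <- list(layers)
  new("LayeredPolarSet", layers = lapply(layers, as.character),
      w = as.integer(w), k = as.integer(k), s = as.numeric(s),
      metadata = metadata)
}

.checkLayers <- function(layers) {
  if (!is.list(layers)) return("layers must be a list of character vectors")
  if (!all(vapply(layers, is.character, logical(1))))
    return("layers must be a list of character vectors")
  all_k <- unlist(layers)
  if (anyDuplicated(all_k)) return("layers must be pairwise disjoint")
  NULL
}

#' Result of applying a minimizer scheme to a sequence
#'
#' Selected k-mer start positions (1-based) plus the bookkeeping needed for
#' density calculations: the number of charged contexts (contexts whose two
#' windows select different positions), windows, contexts, k-mers and
#' break-free fragments. On a break-free sequence the number of selected
#' positions equals the number of charged contexts plus one.
#'
#' @slot positions sorted integer vector of selected positions (1-based).
#' @slot nCharged,nWindows,nContexts,nKmers numeric counts.
#' @slot nFragments,nFragmentsWithWindows numeric fragment counts.
#' @slot w,k integer parameters.
#' @export
setClass("MinimizerSelection",
         representation(positions = "integer", nCharged = "numeric",
                        nWindows = "numeric", nContexts = "numeric",
                        nKmers = "numeric", nFragments = "numeric",
                        nFragmentsWithWindows = "numeric",
                        w = "integer", k = "integer"))

#' Context energies aggregated over a sequence
#'
#' Per-context energies E(c) summarise how a random minimizer behaves: E(c)
#' is the probability the context is charged, equal to 2/u if the last
#' k-mer of the context occurs exactly once in it and 1/u otherwise, with u
#' the number of distinct k-mers among its w + 1 k-mers. The profile stores
#' the initial energy E0 (sum of E(c)), the total deficit D (energy-saver
#' contexts below the 2/(w+1) baseline) and the total surplus X
#' (energy-spender contexts above it).
#'
#' @slot e0,deficit,surplus numeric aggregates.
#' @slot nContexts,nSavers,nSpenders,nKmers,nFragments numeric counts
#'   (\code{nFragments} counts fragments holding at least one window).
#' @slot contexts data.frame of per-context (u, lastUnique, energy) when
#'   requested, else empty.
#' @slot w,k integer parameters.
#' @export
setClass("EnergyProfile",
         representation(e0 = "numeric", deficit = "numeric",
                        surplus = "numeric", nContexts = "numeric",
                        nSavers = "numeric", nSpenders = "numeric",
                        nKmers = "numeric", nFragments = "numeric",
                        contexts = "data.frame", w = "integer",
                        k = "integer"))

#' Link energy statistics of a (layered) polar set on a sequence
#'
#' Uncovered member occurrences form links when consecutive ones lie at
#' most w bases apart; a link of length l carries energy 2l/(w+1) - 1. The
#' same total arises from covered-context bookkeeping as
#' L = 2*Acov/(w+1) - Aele - Aseg, where Acov counts contexts containing an
#' uncovered occurrence, Aele the uncovered occurrences and Aseg the
#' maximal runs of consecutive occurrence-containing windows. Both routes
#' are computed and verified to agree exactly.
#'
#' @slot acov,aele,aseg numeric bookkeeping counts.
#' @slot total numeric total link energy.
#' @slot links data.frame with columns left, right, gap, energy (positions
#'   1-based).
#' @slot elements sorted integer vector of uncovered member occurrences
#'   (1-based).
#' @slot w integer window size.
#' @export
setClass("LinkStats",
         representation(acov = "numeric", aele = "numeric", aseg = "numeric",
                        total = "numeric", links = "data.frame",
                        elements = "integer", w = "integer"))

#' Suffix-array index of a sequence
#'
#' Suffix array, inverse suffix array and LCP heights of the encoded
#' sequence, built once for a fixed k. Supports listing all positions that
#' share the k-mer at a given position in output-linear time
#' (\code{\link{occurrences}}) and per-position occurrence counts used by
#' the frequency filter (\code{\link{frequencyThreshold}}).
#'
#' @slot sa,isa,lcp integer vectors (0-based internals).
#' @slot freq integer occurrence count of the k-mer at each position (0
#'   where no break-free k-mer starts).
#' @slot valid logical: does a break-free k-mer start here.
#' @slot k integer k-mer length the index was built for.
#' @slot n integer sequence length.
#' @export
setClass("SuffixIndex",
         representation(sa = "integer", isa = "integer", lcp = "integer",
                        freq = "integer", valid = "logical", k = "integer",
                        n = "integer"))

#' Linked blocks over selected locations
#'
#' Divides sequence positions into blocks of width floor(w/2), each holding
#' at most one selected location (guaranteed by polar spacing > w/2).
#' Supports nearest-selected queries up to w bases away in constant time
#' and incremental maintenance of the link-energy aggregates (Acov, Aele,
#' Aseg, L) as locations are added and removed. The object has reference
#' semantics: \code{\link{addLocation}} and \code{\link{removeLocation}}
#' mutate it in place.
#'
#' @slot ptr external pointer to the block array.
#' @slot n,w integer sequence length and window size.
#' @export
setClass("LinkedBlocks",
         representation(ptr = "externalptr", n = "integer", w = "integer"))

#' @param n sequence length (number of positions).
#' @param w window size in k-mers.
#' @rdname LinkedBlocks-class
#' @export
LinkedBlocks <- function(n, w) {
  new("LinkedBlocks", ptr = cpp_lb_new(as.integer(n), as.integer(w)),
      n = as.integer(n), w = as.integer(w))
}
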