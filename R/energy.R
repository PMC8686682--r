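#' Energy of a single context
#'
#' The energy of a context is the probability that a uniformly random
#' minimizer order charges it: 2/u if the context's last k-mer occurs
#' exactly once within the context, 1/u otherwise, where u is the number of
#' distinct k-mers among its w + 1 k-mers.
#'
#' @param context either a character string of w + k bases, or a character
#'   vector of the w + 1 k-mers.
#' @param k k-mer length; required when \code{context} is a single string.
#' @return The context energy, a number in (0, 1].
#' @examples
#' contextEnergy("ACGTAC", k = 2)  # u = 4, last k-mer AC repeats: 1/4
#' @export
contextEnergy <- function(context, k = NULL) {
  kmers <- .contextKmers(context, k)
  u <- length(unique(kmers))
  last_unique <- sum(kmers == kmers[length(kmers)]) == 1L
  if (last_unique) 2 / u else 1 / u
}

.contextKmers <- function(context, k) {
  if (length(context) == 1L && !is.null(k) && nchar(context) > k) {
    n <- nchar(context)
    kmers <- substring(context, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  } else {
    kmers <- as.character(context)
  }
  if (length(kmers) < 2) stop("a context needs at least 2 k-mers (w >= 1)")
  if (length(unique(nchar(kmers))) != 1)
    stop("context k-mers must have equal length")
  kmers
}

#' Context-energy profile of a sequence
#'
#' Slides over every context (w + 1 consecutive k-mers) of every break-free
#' fragment, computing the context energy and aggregating the initial
#' energy E0 = sum E(c), the total deficit D = sum max(0, 2/(w+1) - E(c))
#' over energy-saver contexts and the total surplus
#' X = sum max(0, E(c) - 2/(w+1)) over energy spenders. Runs in expected
#' linear time via an occurrence-count sliding window.
#'
#' The expected number of positions selected by a random minimizer equals
#' the number of fragments (holding a window) plus E0; D and X tighten this
#' into the two-sided bound evaluated by \code{\link{densityBounds}}.
#'
#' @inheritParams selectMinimizers
#' @param detail also record per-context (u, lastUnique, energy); only for
#'   small inputs.
#' @return An \linkS4class{EnergyProfile}.
#' @export
energyProfile <- function(x, w, k, detail = FALSE) {
  .checkWK(w, k)
  codes <- .seqCodes(x)
  res <- cpp_energy_profile(codes, as.integer(w), as.integer(k), detail)
  if (res$n_contexts == 0)
    stop("sequence too short: no fragment holds a context of ", w + 1,
         " k-mers (w + k = ", w + k, " bases)")
  ctx <- if (detail) {
    data.frame(u = res$u, lastUnique = res$last_unique == 1,
               energy = res$energy)
  } else {
    data.frame(u = integer(0), lastUnique = logical(0), energy = numeric(0))
  }
  new("EnergyProfile", e0 = res$E0, deficit = res$deficit,
      surplus = res$surplus, nContexts = res$n_contexts,
      nSavers = res$n_savers, nSpenders = res$n_spenders,
      nKmers = res$n_kmers, nFragments = res$n_fragments_with_windows,
      contexts = ctx, w = as.integer(w), k = as.integer(k))
}

#' Monte-Carlo expected number of selected positions
#'
#' Averages the selected-position count over random orders compatible with
#' the given layers (plain random orders when \code{layers} is empty). With
#' no layers the mean estimates 1 + E0(S) on a break-free sequence.
#'
#' @inheritParams selectMinimizers
#' @param layers list of k-mer layers the sampled orders must respect.
#' @param trials number of random orders.
#' @param seed integer seed; per-trial hash seeds are derived from it.
#' @return List with \code{mean}, \code{se} (standard error) and the
#'   per-trial \code{counts}.
#' @export
expectedSelectedMC <- function(x, w, k, layers = list(), trials = 100,
                               seed = 1L) {
  stopifnot(trials >= 1)
  codes <- .seqCodes(x)
  flat <- .flattenLayers(if (is.character(layers)) list(layers) else layers, k)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, trials)
  counts <- vapply(seeds, function(s) {
    res <- cpp_select_positions(codes, as.integer(w), as.integer(k),
                                flat$kmers, flat$ids, s)
    res$n_selected
  }, numeric(1))
  se <- if (trials > 1) stats::sd(counts) / sqrt(trials) else 0
  list(mean = mean(counts), se = se, counts = counts)
}

#' @describeIn EnergyProfile-class total initial energy E0.
#' @param x an \linkS4class{EnergyProfile}.
#' @export
setMethod("initialEnergy", "EnergyProfile", function(x) x@e0)

#' @describeIn EnergyProfile-class total energy deficit D.
#' @export
setMethod("energyDeficit", "EnergyProfile", function(x) x@deficit)

#' @describeIn EnergyProfile-class total energy surplus X.
#' @export
setMethod("energySurplus", "EnergyProfile", function(x) x@surplus)

#' @describeIn EnergyProfile-class number of contexts.
#' @export
setMethod("nContexts", "EnergyProfile", function(x) x@nContexts)

#' @describeIn EnergyProfile-class number of k-mers.
#' @export
setMethod("nKmers", "EnergyProfile", function(x) x@nKmers)

#' @describeIn EnergyProfile-class window size.
#' @export
setMethod("windowSize", "EnergyProfile", function(x) x@w)

#' @describeIn EnergyProfile-class k-mer length.
#' @export
setMethod("kmerSize", "EnergyProfile", function(x) x@k)

setMethod("show", "EnergyProfile", function(object) {
  cat("EnergyProfile (w =", object@w, ", k =", object@k, ")\n")
  cat("  contexts:", format(object@nContexts, big.mark = ","),
      " savers:", object@nSavers, " spenders:", object@nSpenders, "\n")
  cat(sprintf("  E0 = %.6g  (per context %.6g; baseline %.6g)\n",
              object@e0, object@e0 / object@nContexts, 2 / (object@w + 1)))
  cat(sprintf("  deficit D = %.3g   surplus X = %.3g (per context %.3g / %.3g)\n",
              object@deficit, object@surplus,
              object@deficit / object@nContexts,
              object@surplus / object@nContexts))
})
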