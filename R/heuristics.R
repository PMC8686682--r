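#' One round of the polar set heuristic
#'
#' Visits the k-mer positions congruent to \code{offset} modulo w in a
#' seeded shuffled order. Each k-mer is considered only at its first
#' encounter and filtered out when it occurs more than \code{maxFreq}
#' times, collides with itself (two uncovered occurrences closer than the
#' spacing threshold) or sits too close to a previous-layer element.
#' Admissible k-mers are inserted after evicting conflicting current-layer
#' k-mers; in the monotonic variant an insertion is kept only when it
#' strictly increases the total link energy. Members forming no link are
#' pruned at the end.
#'
#' @inheritParams selectMinimizers
#' @param s slackness in [0, 1/2).
#' @param offset congruence class of visited positions, in 0..w-1
#'   (0-based).
#' @param maxFreq occurrence-count cap for candidate k-mers.
#' @param seed shuffle seed.
#' @param monotonic require every kept insertion to strictly increase L.
#' @param prevElements sorted 1-based positions of all previous-layer
#'   elements (uncovered occurrences).
#' @param idx optional precomputed \linkS4class{SuffixIndex} for \code{x}
#'   and \code{k}.
#' @return List: \code{kmers} (the layer), \code{elements} (its uncovered
#'   occurrences, 1-based), the union aggregates \code{acov}, \code{aele},
#'   \code{aseg}, \code{L}, \code{L_before}, a per-acceptance \code{trace}
#'   of L, and visit counters.
#' @export
polarRound <- function(x, w, k, s = 0.4, offset = 0L, maxFreq = Inf,
                       seed = 1L, monotonic = FALSE,
                       prevElements = integer(0), idx = NULL) {
  .checkWK(w, k)
  .checkSlackness(s)
  if (offset < 0 || offset >= w) stop("offset must lie in 0..w-1")
  codes <- .seqCodes(x)
  if (is.null(idx)) idx <- buildSuffixIndex(x, k)
  stopifnot(is(idx, "SuffixIndex"), idx@k == k, idx@n == length(codes))
  mf <- if (is.finite(maxFreq)) as.integer(maxFreq) else .Machine$integer.max
  res <- cpp_polar_round(codes, as.integer(w), as.integer(k), idx@sa,
                         idx@isa, idx@lcp, idx@freq,
                         sort(as.integer(prevElements)) - 1L,
                         .spacingThreshold(w, s), as.integer(offset), mf,
                         as.integer(seed), isTRUE(monotonic))
  res$kmers <- as.character(res$kmers)
  res$elements <- res$elements + 1L
  res
}

#' Build a layered polar set
#'
#' Runs the polar set heuristic for several rounds, each with a fresh
#' random offset and a frequency threshold interpolated between the given
#' percentiles; every round's result becomes a new layer, constructed
#' against the elements of all earlier layers. The last
#' \code{monotonicTail} rounds use the monotonic (first-choice
#' hill-climbing) variant. Link energy never decreases from round to
#' round. All randomness (offsets, shuffles) derives from \code{seed}.
#'
#' @inheritParams selectMinimizers
#' @param s slackness (default 0.4).
#' @param rounds number of rounds/layers (default 7).
#' @param monotonicTail how many final rounds are monotonic (default 2).
#' @param freqPercentiles start and end fraction of positions the
#'   frequency filter keeps, interpolated linearly across rounds (default
#'   0.85 to 0.95).
#' @param seed master seed.
#' @param offsets optional integer vector of per-round offsets (0-based);
#'   by default drawn without replacement when \code{rounds <= w}.
#' @return A \linkS4class{LayeredPolarSet} whose \code{metadata} holds the
#'   build \code{log} (per-round offsets, thresholds, layer sizes and link
#'   energy), the final \code{elements} and the \code{seed}.
#' @examples
#' s <- simulateSequence("uniform", n = 2000, seed = 3)
#' lps <- buildLayeredPolarSet(s, w = 8, k = 10, rounds = 3, seed = 3)
#' lps
#' @export
buildLayeredPolarSet <- function(x, w, k, s = 0.4, rounds = 7L,
                                 monotonicTail = 2L,
                                 freqPercentiles = c(0.85, 0.95),
                                 seed = 1L, offsets = NULL) {
  .checkWK(w, k)
  .checkSlackness(s)
  stopifnot(rounds >= 1, monotonicTail >= 0, monotonicTail <= rounds,
            length(freqPercentiles) == 2,
            all(freqPercentiles > 0 & freqPercentiles <= 1),
            freqPercentiles[1] <= freqPercentiles[2])
  codes <- .seqCodes(x)
  idx <- buildSuffixIndex(x, k)
  set.seed(seed)
  if (is.null(offsets)) {
    offsets <- if (rounds <= w) sample(0:(w - 1L), rounds)
               else sample(0:(w - 1L), rounds, replace = TRUE)
  } else {
    stopifnot(length(offsets) == rounds, all(offsets >= 0 & offsets < w))
  }
  roundSeeds <- sample.int(.Machine$integer.max, rounds)
  pct <- if (rounds == 1) freqPercentiles[1] else
    seq(freqPercentiles[1], freqPercentiles[2], length.out = rounds)

  laylist <- list()
  elements <- integer(0)
  log <- data.frame()
  for (r in seq_len(rounds)) {
    mf <- frequencyThreshold(idx, pct[r])
    mono <- r > rounds - monotonicTail
    res <- polarRound(x, w, k, s = s, offset = offsets[r], maxFreq = mf,
                      seed = roundSeeds[r], monotonic = mono,
                      prevElements = elements, idx = idx)
    if (length(res$kmers) > 0) {
      laylist[[length(laylist) + 1L]] <- sort(res$kmers)
      elements <- sort(c(elements, res$elements))
    }
    log <- rbind(log, data.frame(
      round = r, offset = offsets[r], maxFreq = mf, monotonic = mono,
      percentile = pct[r], nKmers = length(res$kmers),
      nElements = length(res$elements), acov = res$acov, aele = res$aele,
      aseg = res$aseg, L = res$L))
  }
  LayeredPolarSet(laylist, w = w, k = k, s = s,
                  metadata = list(log = log, elements = elements,
                                  seed = as.integer(seed)))
}
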