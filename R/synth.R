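#' Generate synthetic test sequences
#'
#' Deterministic (seeded) generators for the study conditions exercised by
#' the package:
#' \describe{
#'   \item{uniform}{each base drawn uniformly from the first \code{sigma}
#'     letters of ACGT.}
#'   \item{periodic}{a period-\code{w} sequence whose w k-mers are
#'     distinct, the extreme scenario in which every context is an energy
#'     saver.}
#'   \item{planted_perfect}{a uniform sequence in the short-sequence
#'     regime n < epsilon * w * sigma^k / 2, where with probability at
#'     least 1 - epsilon the fixed-interval k-mers occur nowhere else and
#'     a compatible minimizer is perfect; a warning is emitted outside the
#'     regime.}
#'   \item{repeat_mosaic}{blocks copied from a short core sequence, so
#'     many k-mers are frequent.}
#' }
#'
#' @param kind one of "uniform", "periodic", "planted_perfect",
#'   "repeat_mosaic".
#' @param n sequence length in bases.
#' @param sigma alphabet size (2..4; uses the first sigma letters of
#'   ACGT).
#' @param w,k parameters needed by the periodic and planted kinds.
#' @param seed integer seed.
#' @param blockLen repeat_mosaic block length.
#' @param epsilon failure budget of the perfect-seed regime check.
#' @return A character string of length \code{n}.
#' @export
simulateSequence <- function(kind = c("uniform", "periodic",
                                      "planted_perfect", "repeat_mosaic"),
                             n, sigma = 4, w = NULL, k = NULL, seed = 1L,
                             blockLen = 50L, epsilon = 0.01) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, sigma >= 2, sigma <= 4)
  alphabet <- c("A", "C", "G", "T")[seq_len(sigma)]
  set.seed(seed)
  switch(kind,
    uniform = paste(sample(alphabet, n, replace = TRUE), collapse = ""),
    periodic = {
      if (is.null(w) || is.null(k)) stop("periodic kind needs w and k")
      .checkWK(w, k)
      if (k == 1 && sigma < w)
        stop("periodic with k = 1 needs sigma >= w for distinct k-mers")
      for (i in 1:10000) {
        per <- if (k == 1) sample(alphabet, w) else
          sample(alphabet, w, replace = TRUE)
        ext <- paste(rep(per, length.out = w + k - 1), collapse = "")
        kms <- substring(ext, seq_len(w), seq_len(w) + k - 1)
        if (!anyDuplicated(kms)) break
        if (i == 10000)
          stop("could not find a period with w distinct k-mers; ",
               "increase sigma or k")
      }
      paste(rep(per, length.out = n), collapse = "")
    },
    planted_perfect = {
      if (is.null(w) || is.null(k)) stop("planted_perfect kind needs w and k")
      .checkWK(w, k)
      limit <- epsilon * w * sigma^k / 2
      if (n >= limit)
        warning("n = ", n, " is not in the perfect-seed regime ",
                "(needs n < epsilon * w * sigma^k / 2 = ",
                format(limit), "); perfect seeds are unlikely")
      paste(sample(alphabet, n, replace = TRUE), collapse = "")
    },
    repeat_mosaic = {
      blockLen <- max(2L, as.integer(blockLen))
      coreLen <- max(2L * blockLen, ceiling(n / 5))
      core <- sample(alphabet, coreLen, replace = TRUE)
      out <- character(0)
      while (length(out) < n) {
        st <- sample.int(coreLen - blockLen + 1L, 1L)
        out <- c(out, core[st:(st + blockLen - 1L)])
      }
      paste(out[seq_len(n)], collapse = "")
    })
}

#' Fixed-interval k-mer set
#'
#' The set of k-mers occurring at positions congruent to \code{offset}
#' modulo w (0-based). On a sequence where these k-mers occur nowhere
#' else, a compatible minimizer selects exactly the grid positions and is
#' perfect (density 1/w).
#'
#' @inheritParams selectMinimizers
#' @param offset grid offset in 0..w-1 (0-based).
#' @return Character vector of unique k-mers.
#' @export
fixedIntervalSet <- function(x, w, k, offset = 0L) {
  .checkWK(w, k)
  if (offset < 0 || offset >= w) stop("offset must lie in 0..w-1")
  records <- .seqRecords(x)
  seqstr <- paste(records, collapse = "N")
  codes <- cpp_encode_records(seqstr)
  valid <- cpp_valid_starts(codes, as.integer(k))
  t0 <- seq.int(offset + 1L, length(codes), by = w)   # 1-based grid
  t0 <- t0[valid[t0]]
  if (length(t0) == 0) return(character(0))
  unique(toupper(substring(seqstr, t0, t0 + k - 1L)))
}
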