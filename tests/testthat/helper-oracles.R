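# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: windowing is done by naive per-window scans,
# permutations by explicit enumeration, link statistics by direct interval
# unions.

random_dna <- function(n, sigma = 4, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T")[seq_len(sigma)], n, replace = TRUE),
        collapse = "")
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

# exact charged probability of a context under a uniformly random order:
# enumerate all permutations of its distinct k-mers
oracle_context_energy <- function(kmers) {
  w <- length(kmers) - 1L
  uk <- unique(kmers)
  id <- match(kmers, uk)
  charged <- 0L
  perms <- all_perms(length(uk))
  for (p in perms) {
    r <- p[id]
    sel1 <- which.min(r[1:w])
    sel2 <- which.min(r[2:(w + 1)]) + 1L
    if (sel1 != sel2) charged <- charged + 1L
  }
  charged / length(perms)
}

# naive minimizer application: every window scanned independently with
# selectInWindow (shared rank primitive, independent windowing/counting)
oracle_select <- function(s, w, k, order) {
  kms <- seq_kmers(s, k)
  nk <- length(kms)
  sel <- integer(0)
  for (t in seq_len(nk - w + 1)) {
    win <- kms[t:(t + w - 1)]
    sel <- c(sel, t - 1L + selectInWindow(win, order))
  }
  list(positions = sort(unique(sel)),
       charged = sum(sel[-1] != sel[-length(sel)]))
}

oracle_occurrences <- function(s, t, k) {
  kms <- seq_kmers(s, k)
  which(kms == kms[t])
}

# from-scratch link statistics from sorted element positions (1-based):
# acov via explicit interval union, aseg via runs, L via pairwise sum
oracle_link_stats <- function(pos, w) {
  pos <- sort(pos)
  if (length(pos) == 0)
    return(list(acov = 0, aele = 0, aseg = 0, L = 0))
  cov <- unique(unlist(lapply(pos, function(p) (p - w):p)))
  gaps <- diff(pos)
  linked <- gaps <= w
  list(acov = length(cov), aele = length(pos),
       aseg = 1 + sum(!linked),
       L = sum(2 * gaps[linked] / (w + 1) - 1))
}

# brute-force layered polar set check straight from the definition
oracle_validate_layered <- function(s, lps) {
  w <- windowSize(lps); thr <- spacingThreshold(lps)
  lay <- layers(lps)
  kms <- seq_kmers(s, kmerSize(lps))
  occ <- lapply(lay, function(A) sort(which(kms %in% A)))
  for (j in seq_along(lay)) {
    prev <- sort(unlist(occ[seq_len(j - 1)]))
    upto <- sort(unlist(occ[seq_len(j)]))
    for (t in occ[[j]]) {
      covered <- FALSE
      for (l in prev) for (h in prev)
        if (l < t && t < h && h - l <= w) covered <- TRUE
      if (covered) next
      others <- setdiff(upto, t)
      if (length(others) > 0 && min(abs(others - t)) < thr) return(FALSE)
    }
  }
  TRUE
}
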