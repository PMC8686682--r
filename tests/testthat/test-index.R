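test_that("suffix array matches the sorted-suffix oracle", {
  set.seed(13)
  for (i in 1:12) {
    n <- sample(20:300, 1)
    s <- random_dna(n, sample(c(2, 4), 1), seed = sample.int(1e6, 1))
    if (i %% 3 == 0) {  # inject breaks
      p <- sample(nchar(s), 2)
      substr(s, p[1], p[1]) <- "N"
      substr(s, p[2], p[2]) <- "N"
    }
    codes <- polarmin:::.seqCodes(s)
    sar <- polarmin:::cpp_suffix_array(codes)
    chars <- c(".", "A", "C", "G", "T")[ifelse(codes < 0, 0L, codes + 1L) + 1L]
    str <- paste(chars, collapse = "")
    suff <- substring(str, seq_len(n), n)
    expect_identical(sar$sa + 1L, order(suff, method = "radix"))
    expect_identical(sar$isa[sar$sa + 1L], 0:(n - 1L))
    # LCP heights against direct prefix comparison
    for (r in seq(2, n, by = max(1, n %/% 15))) {
      x <- strsplit(suff[sar$sa[r - 1] + 1], "")[[1]]
      y <- strsplit(suff[sar$sa[r] + 1], "")[[1]]
      m <- min(length(x), length(y))
      lcp2 <- which(x[1:m] != y[1:m])[1] - 1
      if (is.na(lcp2)) lcp2 <- m
      expect_equal(sar$lcp[r], lcp2)
    }
  }
})

test_that("occurrence queries equal a naive substring scan", {
  expect_identical(occurrences(buildSuffixIndex("ACGTACGT", k = 4), 1),
                   c(1L, 5L))
  set.seed(29)
  for (i in 1:20) {
    s <- random_dna(sample(40:200, 1), sample(c(2, 4), 1),
                    seed = sample.int(1e6, 1))
    k <- sample(2:5, 1)
    idx <- buildSuffixIndex(s, k)
    nk <- nchar(s) - k + 1
    for (t in sample(nk, min(12, nk))) {
      expect_identical(occurrences(idx, t), oracle_occurrences(s, t, k))
    }
  }
  # unique k-mer: singleton result
  s <- "ACGTGGTTAC"
  idx <- buildSuffixIndex(s, 5)
  expect_identical(occurrences(idx, 2), 2L)
  expect_error(occurrences(idx, 0), "out of range")
})

test_that("indexed k-mer frequencies match direct counting", {
  for (i in 1:6) {
    s <- random_dna(150, 2, seed = i + 90)
    k <- 3
    idx <- buildSuffixIndex(s, k)
    kms <- seq_kmers(s, k)
    expect_identical(idx@freq[idx@valid],
                     as.integer(table(kms)[kms]))
  }
})

test_that("peeks agree with a linear scan over selected locations", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(60:200, 1)
    w <- sample(4:12, 1)
    thr <- floor(w / 2) + 1
    pos <- cumsum(c(sample(1:10, 1), sample(thr:(2 * w), 12, replace = TRUE)))
    pos <- pos[pos <= n]
    lb <- LinkedBlocks(n, w)
    for (p in pos) addLocation(lb, p)
    for (x in sample(n, 25)) {
      inl <- pos[pos <= x & pos >= x - w]
      inr <- pos[pos >= x & pos <= x + w]
      expect_identical(peekLeft(lb, x),
                       if (length(inl)) max(inl) else NA_integer_)
      expect_identical(peekRight(lb, x),
                       if (length(inr)) min(inr) else NA_integer_)
    }
  }
})

test_that("insertion deltas match the worked cases", {
  w <- 10
  lb <- LinkedBlocks(200, w)
  # isolated insertion: dAcov = w+1, dAele = dAseg = 1, dL = 0
  addLocation(lb, 100)
  st <- blockStats(lb)
  expect_equal(st$acov, w + 1)
  expect_equal(st$aele, 1)
  expect_equal(st$aseg, 1)
  expect_identical(st$L, 0)
  # insertion at distance exactly w: dL = 1 - 2/(w+1)
  addLocation(lb, 110)
  expect_equal(blockStats(lb)$L, 1 - 2 / (w + 1))
  # add followed by remove restores the aggregates exactly
  addLocation(lb, 123)
  removeLocation(lb, 123)
  st2 <- blockStats(lb)
  expect_equal(st2$L, 1 - 2 / (w + 1))
  expect_equal(st2$aele, 2)
  # occupied-block add and absent remove are contract violations
  expect_error(addLocation(lb, 101), "occupied|spacing")
  expect_error(removeLocation(lb, 50), "not selected")
  # spacing violations are refused
  expect_error(addLocation(lb, 114), "spacing")
})

test_that("incremental aggregates always equal from-scratch recomputation", {
  set.seed(53)
  n <- 3000; w <- 9
  thr <- floor(w / 2) + 1
  lb <- LinkedBlocks(n, w)
  current <- integer(0)
  for (op in 1:2000) {
    if (length(current) > 0 && runif(1) < 0.4) {
      p <- current[sample.int(length(current), 1)]
      removeLocation(lb, p)
      current <- setdiff(current, p)
    } else {
      p <- sample(n, 1)
      near <- current[abs(current - p) < thr]
      if (length(near) > 0) next
      addLocation(lb, p)
      current <- c(current, p)
    }
    if (op %% 20 == 0) {
      st <- blockStats(lb)
      o <- oracle_link_stats(current, w)
      expect_identical(st$acov, as.numeric(o$acov))
      expect_identical(st$aele, as.numeric(o$aele))
      expect_identical(st$aseg, as.numeric(o$aseg))
      expect_lt(abs(st$L - o$L), 1e-9)
      expect_setequal(selectedLocations(lb), current)
    }
  }
})
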