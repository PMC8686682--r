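# sequence with all 6-mers distinct (checked), handy for spacing fixtures
unique_seq <- function(n = 40, seed = 11) {
  s <- simulateSequence("uniform", n = n, seed = seed)
  stopifnot(!anyDuplicated(seq_kmers(s, 6)))
  s
}

test_that("polar spacing validation matches the definition", {
  # ACGTT at positions 3 and 8: gap 5 below the w=10, s=0.4 threshold of 6
  bad <- "AAACGTTACGTTCCCAAA"
  v <- validatePolar(bad, "ACGTT", w = 10, s = 0.4)
  expect_false(v$valid)
  expect_equal(nrow(v$violations), 1)
  expect_equal(v$violations$gap, 5)
  expect_equal(v$threshold, 6)
  # occurrences exactly (1-s)w apart are accepted (inclusive rule)
  good <- "AAACGTTGAACGTTCCCA"   # gap 7 >= 6... place exactly 6
  s6 <- paste0("AA", "ACGTT", "C", "ACGTT", "GGGGG")  # gap 6
  v2 <- validatePolar(s6, "ACGTT", w = 10, s = 0.4)
  expect_equal(diff(which(seq_kmers(s6, 5) == "ACGTT")), 6)
  expect_true(v2$valid)
  # empty set is vacuously polar
  expect_true(validatePolar(bad, character(0), 10, 0.4)$valid)
  # slackness contract
  expect_error(validatePolar(bad, "ACGTT", 10, 0.5), "slackness")
})

test_that("single-layer validation degenerates to the plain polar check", {
  set.seed(8)
  for (i in 1:20) {
    s <- random_dna(120, 4, seed = sample.int(1e6, 1))
    kms <- unique(seq_kmers(s, 4))
    A <- sample(kms, 3)
    w <- sample(4:8, 1)
    vp <- validatePolar(s, A, w, s = 0.4)
    vl <- validateLayered(s, LayeredPolarSet(list(A), w = w, k = 4, s = 0.4))
    expect_identical(vp$valid, vl$valid)
  }
})

test_that("covered later-layer occurrences are accepted regardless of spacing", {
  s <- unique_seq()
  kms <- seq_kmers(s, 6)
  # layer-1 k-mers at positions 10 and 18 (8 <= w = 10 apart) sandwich a
  # layer-2 k-mer at 14, which sits closer than the threshold to both
  lps <- LayeredPolarSet(list(kms[c(10, 18)], kms[14]), w = 10, k = 6,
                         s = 0.4)
  v <- validateLayered(s, lps)
  expect_true(v$valid)
  expect_true(oracle_validate_layered(s, lps))
  # without the covering layer the same k-mer violates the spacing
  lps2 <- LayeredPolarSet(list(kms[c(14, 18)]), w = 10, k = 6, s = 0.4)
  expect_false(validateLayered(s, lps2)$valid)
})

test_that("three-layer construction validates and collapses without layer 1", {
  s <- unique_seq(60, seed = 20)
  kms <- seq_kmers(s, 6)
  # w = 4, s = 0.4 -> threshold 3. Layer 1 at 10, 14; layer 2 at 11 and 12
  # (both covered by 10 < t < 14); layer 3 at 17 (uncovered, spacing 3).
  lps <- LayeredPolarSet(list(kms[c(10, 14)], kms[c(11, 12)], kms[17]),
                         w = 4, k = 6, s = 0.4)
  expect_true(validateLayered(s, lps)$valid)
  expect_true(oracle_validate_layered(s, lps))
  # dropping layer 1 orphans layer 2: 11 and 12 are 1 apart and uncovered
  lps2 <- LayeredPolarSet(list(kms[c(11, 12)], kms[17]), w = 4, k = 6,
                          s = 0.4)
  expect_false(validateLayered(s, lps2)$valid)
  expect_false(oracle_validate_layered(s, lps2))
})

test_that("validation verdicts agree with the brute-force definition", {
  set.seed(303)
  for (i in 1:25) {
    s <- random_dna(100, 4, seed = sample.int(1e6, 1))
    kms <- unique(seq_kmers(s, 3))
    nl <- sample(1:3, 1)
    lay <- split(sample(kms, min(6, length(kms))),
                 rep(seq_len(nl), length.out = min(6, length(kms))))
    lps <- LayeredPolarSet(unname(lay), w = sample(4:8, 1), k = 3, s = 0.4)
    expect_identical(validateLayered(s, lps)$valid,
                     oracle_validate_layered(s, lps))
  }
})

test_that("the three-k-mer link fixture gives energies 0 and 1/3", {
  s <- unique_seq()
  kms <- seq_kmers(s, 6)
  A <- kms[c(15, 18, 22)]  # gaps 3 and 4, away from the ends, w = 5
  lps <- LayeredPolarSet(list(A), w = 5, k = 6, s = 0.4)
  ls <- linkEnergy(s, lps)
  expect_equal(linkTable(ls)$energy, c(0, 1 / 3))
  expect_equal(totalLinkEnergy(ls), 1 / 3)
  expect_equal(ls@acov, 13)
  expect_equal(ls@aele, 3)
  expect_equal(ls@aseg, 1)
  expect_equal(2 * 13 / 6 - 3 - 1, 1 / 3)
})

test_that("an isolated polar occurrence carries zero link energy", {
  s <- unique_seq()
  kms <- seq_kmers(s, 6)
  ls <- linkEnergy(s, LayeredPolarSet(list(kms[20]), w = 5, k = 6, s = 0.4))
  expect_equal(ls@acov, 5 + 1)
  expect_equal(ls@aele, 1)
  expect_equal(ls@aseg, 1)
  expect_identical(totalLinkEnergy(ls), 0)
  expect_equal(nrow(linkTable(ls)), 0)
})

test_that("pairwise and covered-context link formulas agree exactly", {
  set.seed(19)
  for (i in 1:40) {
    w <- sample(4:12, 1)
    thr <- floor(w / 2) + 1
    # random element set respecting polar spacing > w/2
    pos <- cumsum(c(sample(20:40, 1), sample(thr:(3 * w), sample(3:15, 1),
                                             replace = TRUE)))
    st <- polarmin:::.linkStatsFromElements(pos, w)
    o <- oracle_link_stats(pos, w)
    expect_identical(st@acov, as.numeric(o$acov))
    expect_identical(st@aele, as.numeric(o$aele))
    expect_identical(st@aseg, as.numeric(o$aseg))
    expect_lt(abs(st@total - o$L), 1e-12)
    expect_lt(abs(st@total -
                  (2 * st@acov / (w + 1) - st@aele - st@aseg)), 1e-12)
  }
})

test_that("link energy never decreases as layers are added", {
  for (i in 1:5) {
    s <- simulateSequence("repeat_mosaic", 1500, seed = i, blockLen = 40)
    lps <- buildLayeredPolarSet(s, w = 8, k = 8, rounds = 4, seed = i)
    lay <- layers(lps)
    if (length(lay) < 2) next
    L <- vapply(seq_along(lay), function(j) {
      totalLinkEnergy(linkEnergy(s, LayeredPolarSet(lay[seq_len(j)],
                                                    w = 8, k = 8, s = 0.4)))
    }, numeric(1))
    expect_true(all(diff(L) >= -1e-9))
  }
})

test_that("no window of a valid polar set contains two member occurrences", {
  set.seed(71)
  for (i in 1:10) {
    s <- random_dna(400, 4, seed = sample.int(1e6, 1))
    lps <- buildLayeredPolarSet(s, w = 6, k = 6, rounds = 1,
                                monotonicTail = 0, seed = i)
    lay <- layers(lps)
    if (length(lay) == 0) next
    occ <- sort(which(seq_kmers(s, 6) %in% lay[[1]]))
    if (length(occ) > 1) expect_gt(min(diff(occ)), 6 / 2)
  }
})

test_that("expected selection is sandwiched by the density bounds", {
  set.seed(99)
  checked <- 0
  for (i in 1:50) {
    n <- sample(300:900, 1)
    w <- sample(4:12, 1)
    s <- simulateSequence(sample(c("uniform", "repeat_mosaic"), 1), n = n,
                          seed = sample.int(1e6, 1), blockLen = 35)
    lps <- buildLayeredPolarSet(s, w = w, k = 8, rounds = 3,
                                monotonicTail = 1, seed = sample.int(1e6, 1))
    if (length(layers(lps)) == 0) next
    b <- densityBounds(s, lps)
    mc <- expectedSelectedMC(s, w, 8, layers(lps), trials = 120,
                             seed = sample.int(1e6, 1))
    expect_gte(mc$mean, b$count[["lower"]] - 3 * mc$se - 1e-9)
    expect_lte(mc$mean, b$count[["upper"]] + 3 * mc$se + 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("empty polar sets reduce the bounds to the random baseline", {
  s <- random_dna(500, 4, seed = 5)
  lps <- LayeredPolarSet(list(), w = 6, k = 5, s = 0.4)
  ep <- energyProfile(s, 6, 5)
  b <- densityBounds(s, lps, profile = ep)
  expect_equal(b$count[["lower"]],
               1 + initialEnergy(ep) - energySurplus(ep))
  expect_equal(b$count[["upper"]],
               1 + initialEnergy(ep) + energyDeficit(ep))
  expect_identical(b$L, 0)
})

test_that("link energy refuses invalid layered sets", {
  bad <- "AAACGTTACGTTCCCAAA"
  lps <- LayeredPolarSet(list("ACGTT"), w = 10, k = 5, s = 0.4)
  expect_error(linkEnergy(bad, lps), "invalid")
})
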