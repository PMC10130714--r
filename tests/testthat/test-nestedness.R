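test_that("turnoverObserved scores textbook matrices correctly", {
  checker <- rbind(c(1, 0), c(0, 1))
  expect_equal(turnoverObserved(checker), 1)
  nested <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_equal(turnoverObserved(nested), 0)
  # two disjoint intervals over three sites: species A rows 1-2, B rows 2-3
  # pairs (r1, r3) show A->B replacement: exactly one replacement pair
  m <- rbind(c(1, 0), c(1, 1), c(0, 1))
  expect_equal(turnoverObserved(m), 1)
  expect_message(expect_equal(turnoverObserved(matrix(1, 3, 3)), 0),
                 "saturated")
  expect_error(turnoverObserved(matrix(1, 1, 3)))
})

test_that("fillEmbeddedAbsences closes interior gaps only", {
  m <- rbind(c(1, 0), c(0, 0), c(1, 1))
  f <- fillEmbeddedAbsences(m)
  expect_equal(f[, 1], c(1, 1, 1))  # gap at row 2 filled
  expect_equal(f[, 2], c(0, 0, 1))  # no gap, untouched
})

test_that("filling embedded absences can remove spurious replacements", {
  # without filling, the hole in species A at row 2 pairs with B's presence
  m <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_gt(turnoverObserved(m, fillEmbedded = FALSE), 0)
  expect_equal(turnoverObserved(m, fillEmbedded = TRUE), 0)
})

test_that("adjacentOnly counts consecutive-site replacements", {
  # A occupies rows 1-2, B rows 3-4: replacement only at the 2-3 boundary
  m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(turnoverObserved(m, adjacentOnly = TRUE), 1)
  expect_equal(turnoverObserved(m, adjacentOnly = FALSE), 4)  # all 2x2 pairs
})

test_that("r1 null preserves row sums exactly in every replicate", {
  set.seed(42)
  m <- matrix(as.numeric(runif(40) < 0.5), 5, 8)
  m[1, ] <- c(1, rep(0, 7))
  richness <- rowSums(m)
  draws <- replicate(200, phylogradient:::.r1Sample(richness, colSums(m) + 0.5))
  expect_true(all(apply(draws, 3, rowSums) == richness))
})

test_that("r1 column selection follows the marginal weights (chi-squared, 5x8 fixture)", {
  # 5 sites x 8 lineages; the richness-1 row has exactly proportional
  # inclusion probabilities, so a goodness-of-fit test is exactly calibrated
  m <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
             c(1, 1, 0, 0, 0, 0, 0, 0),
             c(1, 1, 1, 1, 0, 0, 0, 0),
             c(1, 1, 1, 1, 1, 1, 0, 0),
             c(1, 1, 1, 1, 1, 1, 1, 1))
  w <- colSums(m)  # 5 4 3 3 2 2 1 1
  set.seed(7)
  reps <- 10000
  hits <- integer(8)
  for (i in seq_len(reps)) {
    d <- phylogradient:::.r1Sample(rowSums(m), w)
    hits <- hits + (d[1, ] > 0)  # the richness-1 site
  }
  gof <- suppressWarnings(stats::chisq.test(hits, p = w / sum(w)))
  expect_gt(gof$p.value, 0.01)
  # and the uniform-weight case is exactly calibrated for every row
  set.seed(8)
  hitsAll <- integer(8)
  for (i in seq_len(2000)) {
    d <- phylogradient:::.r1Sample(c(3, 3, 3, 3, 3), rep(2, 8))
    hitsAll <- hitsAll + colSums(d)
  }
  gof2 <- stats::chisq.test(hitsAll, p = rep(1 / 8, 8))
  expect_gt(gof2$p.value, 0.01)
})

test_that("r1Null is reproducible under a seed and matches vegan's r1 design", {
  set.seed(12)
  m <- matrix(as.numeric(runif(48) < 0.5), 6, 8)
  m[rowSums(m) == 0, 1] <- 1
  m[, colSums(m) == 0][1, ] <- 1
  a <- r1Null(m, replicates = 50, seed = 99)
  b <- r1Null(m, replicates = 50, seed = 99)
  expect_identical(a, b)
  # vegan's "r1" commsim: same invariants (fixed row sums, marginal weights)
  nm <- vegan::nullmodel(m, "r1")
  sims <- simulate(nm, nsim = 30, seed = 1)
  expect_true(all(apply(sims, 3, rowSums) == rowSums(m)))
})

test_that("nestednessTest flags verdicts in both directions", {
  # strongly nested intervals over 8 bins, all sharing an interior core
  bins <- 8
  mk <- function(lo, hi) { v <- numeric(bins); v[lo:hi] <- 1; v }
  nestedM <- cbind(mk(1, 8), mk(2, 8), mk(2, 7), mk(3, 7), mk(3, 6),
                   mk(4, 6), mk(4, 5), mk(4, 5), mk(5, 5), mk(5, 5))
  obs <- turnoverObserved(nestedM)
  expect_equal(obs, 0)
  null <- r1Null(nestedM, replicates = 500, seed = 3)
  expect_gt(mean(null), 0)
  # a banded turnover matrix scores above its null mean
  band <- cbind(mk(1, 2), mk(1, 2), mk(2, 3), mk(3, 4), mk(3, 5),
                mk(4, 6), mk(5, 7), mk(6, 8), mk(7, 8), mk(7, 8))
  expect_gt(turnoverObserved(band),
            mean(r1Null(band, replicates = 300, seed = 4)))
})

test_that("nestednessTest returns a complete per-depth table", {
  cfg <- syntheticConfig(seed = 11, nSpecies = 60)
  sim <- suppressMessages(simulateCommunity(cfg))
  nt <- nestednessTest(sim$tree, sim$grid, depths = c(30, 60, 135),
                       replicates = 100, seed = 11)
  expect_equal(nt$age, c(30, 60, 135))
  expect_equal(names(nt),
               c("age", "nLineages", "observed", "nullMean", "nullSd", "z",
                 "pEmpirical", "pNormal", "verdict", "replicates", "childSeed"))
  expect_true(all(nt$verdict %in%
                  c("nested", "turnover", "indeterminate", "untestable")))
  expect_true(all(nt$nLineages[1] >= nt$nLineages[2]))
  # deterministic under the same top-level seed
  nt2 <- nestednessTest(sim$tree, sim$grid, depths = c(30, 60, 135),
                        replicates = 100, seed = 11)
  expect_identical(nt, nt2)
})

test_that("noise-free nested-mode ranges on the plain linear gradient give zero turnover at all depths", {
  cfg <- syntheticConfig(seed = 5, nSpecies = 80, noise = 0,
                         envNoiseSd = c(cwd = 0, map = 0),
                         cwdPeakFrac = 0, cwdTipDip = 0)
  sim <- suppressMessages(simulateCommunity(cfg))
  binned <- binByLatitude(sim$grid)
  for (t in c(10, 40, 70, 100, 130)) {
    L <- lineagePresenceAtDepth(sim$tree, binned, t)
    if (ncol(L) < 2) next
    expect_equal(suppressMessages(turnoverObserved(L)), 0)
  }
})
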