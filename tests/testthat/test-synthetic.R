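test_that("syntheticConfig validates its arguments", {
  cfg <- syntheticConfig(seed = 4)
  expect_s3_class(cfg, "syntheticConfig")
  expect_equal(cfg$mode, "nested")
  expect_equal(cfg$splitTimes, "expected")
  expect_error(syntheticConfig(nSpecies = 1))
  expect_error(syntheticConfig(cwdRange = c(100, -900)))
  expect_error(syntheticConfig(mode = "banana"))
  expect_error(syntheticConfig(noise = 1.2))
  expect_error(syntheticConfig(cwdPeakFrac = 1))
  expect_error(syntheticConfig(
    lttAnchors = data.frame(age = c(135, 0), n = c(10, 5))))  # not increasing
  expect_error(syntheticConfig(
    lttAnchors = data.frame(age = c(135, 10), n = c(3, 470))))  # no present row
})

test_that("simulateTree yields a valid ultrametric tree of the right size", {
  cfg <- syntheticConfig(seed = 1, nSpecies = 120)
  tree <- simulateTree(cfg)
  expect_equal(ape::Ntip(tree), 120)
  expect_equal(rootAge(tree), 135, tolerance = 1e-9)
  expect_invisible(validateTimeTree(tree))
  # basal polytomy with the configured number of root children
  expect_equal(lineageCount(sliceLineages(tree, 135)), 3)
  expect_equal(tree$tip.label[1], "sp001")
})

test_that("simulateTree is deterministic in the seed and sensitive to it", {
  cfg <- syntheticConfig(seed = 10, nSpecies = 50)
  t1 <- simulateTree(cfg)
  t2 <- simulateTree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulateTree(syntheticConfig(seed = 11, nSpecies = 50))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("expected split times track the lineage-through-time template", {
  cfg <- syntheticConfig(seed = 6)  # 300 species, published anchor template
  tree <- simulateTree(cfg)
  counts <- lttCounts(tree, c(120, 90, 60, 30, 10))
  # template (rescaled in log space from 470 to 300 extant): counts at the
  # anchor depths must sit within a couple lineages of the rescaled curve
  anc <- cfg$lttAnchors
  rescaled <- exp(log(anc$n / anc$n[1]) *
                  log(300 / 3) / log(max(anc$n) / anc$n[1])) * 3
  want <- rescaled[match(c(120, 90, 60, 30, 10), anc$age)]
  expect_true(all(abs(counts - want) <= pmax(2, 0.08 * want)))
})

test_that("stochastic Yule mode reproduces known shape combinatorics", {
  # for a 4-tip Yule tree the balanced shape has probability 1/3
  balanced <- 0L
  for (seed in 1:300) {
    cfg <- syntheticConfig(seed = seed, nSpecies = 4, basalLineages = 2,
                           birthDecay = 0, lttAnchors = NULL,
                           splitTimes = "stochastic")
    tree <- simulateTree(cfg)
    sl <- sliceLineages(tree, rootAge(tree))
    if (all(lengths(lineageTips(sl)) == 2)) balanced <- balanced + 1L
  }
  # binomial(300, 1/3): mean 100, sd 8.2; allow 4 sigma
  expect_gt(balanced, 67)
  expect_lt(balanced, 133)
})

test_that("simulateLandscape produces the documented gradient shapes", {
  cfg <- syntheticConfig(seed = 2, envNoiseSd = c(cwd = 0, map = 0))
  L <- simulateLandscape(cfg)
  expect_equal(nrow(L$coords), cfg$nLatRows * cfg$nLonCols)
  expect_equal(names(L$env), c("cell", "CWD", "MAP", "TRI"))
  expect_true(all(L$env$CWD <= 0))
  expect_true(all(L$env$TRI >= 0))
  byRow <- tapply(L$env$CWD, L$coords$lat, mean)
  peak <- which.max(byRow)
  # interior wet peak: drier at the southern tip and monotone drier north
  expect_gt(peak, 1)
  expect_lt(peak, length(byRow))
  # the wettest row sits near (not exactly at) the peak fraction because
  # row centroids need not coincide with it
  expect_gt(max(byRow), cfg$cwdRange[1] - 100)
  expect_true(all(diff(byRow[peak:length(byRow)]) < 0))
  expect_lt(byRow[1], byRow[peak])
  # MAP declines northward
  mapRow <- tapply(L$env$MAP, L$coords$lat, mean)
  expect_true(all(diff(mapRow) < 0))
})

test_that("cwdPeakFrac = 0 restores the plain linear gradient", {
  cfg <- syntheticConfig(seed = 2, envNoiseSd = c(cwd = 0, map = 0),
                         cwdPeakFrac = 0)
  L <- simulateLandscape(cfg)
  byRow <- tapply(L$env$CWD, L$coords$lat, mean)
  expect_true(all(diff(byRow) < 0))
  expect_equal(unname(byRow[1]), max(byRow))
})

test_that("nested-mode noise-free ranges are ordered by containment", {
  cfg <- syntheticConfig(seed = 13, nSpecies = 60, noise = 0)
  sim <- suppressMessages(simulateCommunity(cfg))
  P <- presenceMatrix(sim$grid)
  thr <- sim$tolerance[colnames(P)]
  ord <- order(thr)  # most tolerant (most negative threshold) first
  for (k in seq_len(length(ord) - 1)) {
    wide <- P[, ord[k]]; narrow <- P[, ord[k + 1]]
    expect_true(all(wide >= narrow))
  }
})

test_that("occupancy noise never moves a species' latitudinal range limits", {
  cfgN <- syntheticConfig(seed = 17, nSpecies = 80, noise = 0.1)
  cfg0 <- syntheticConfig(seed = 17, nSpecies = 80, noise = 0)
  simN <- suppressMessages(simulateCommunity(cfgN))
  sim0 <- suppressMessages(simulateCommunity(cfg0))
  latN <- latitudes(simN$grid); lat0 <- latitudes(sim0$grid)
  PN <- presenceMatrix(simN$grid); P0 <- presenceMatrix(sim0$grid)
  for (s in colnames(P0)) {
    expect_equal(range(latN[PN[, s] > 0]), range(lat0[P0[, s] > 0]))
  }
})

test_that("turnover mode occupies bounded climatic intervals", {
  cfg <- syntheticConfig(seed = 19, nSpecies = 60, noise = 0,
                         mode = "turnover")
  sim <- suppressMessages(simulateCommunity(cfg))
  P <- presenceMatrix(sim$grid)
  cwd <- sim$landscape$env$CWD
  thr <- sim$tolerance[colnames(P)]
  for (s in sample(colnames(P), 20)) {
    occ <- P[, s] > 0
    inBand <- abs(cwd - thr[s]) <= cfg$toleranceWidth / 2
    widened <- thr[s] == max(cwd)
    if (!widened) expect_equal(occ, inBand, ignore_attr = TRUE)
  }
})

test_that("cladeMapFromSlices labels are monophyletic partitions", {
  cfg <- syntheticConfig(seed = 23, nSpecies = 40)
  tree <- simulateTree(cfg)
  cm <- cladeMapFromSlices(tree)
  expect_equal(sort(cm$species), sort(tree$tip.label))
  expect_equal(length(unique(cm$superorder)), 3)  # the basal lineages
  # every family nests inside exactly one superorder
  nesting <- tapply(cm$superorder, cm$family,
                    function(x) length(unique(x)))
  expect_true(all(nesting == 1))
  # families are the 60-Myr lineages
  expect_equal(length(unique(cm$family)),
               lineageCount(sliceLineages(tree, 60)))
})

test_that("simulateCommunity bundles consistent components", {
  cfg <- syntheticConfig(seed = 29, nSpecies = 50)
  sim <- suppressMessages(simulateCommunity(cfg))
  expect_equal(sort(sim$tree$tip.label), sort(speciesNames(sim$grid)))
  expect_equal(names(sim$observedLat), speciesNames(sim$grid))
  expect_true(all(lengths(sim$observedLat) >= 1))
  expect_true(all(lengths(sim$observedLat) <= 5))
  # observed latitudes are latitudes of occupied cells
  lat <- latitudes(sim$grid)
  P <- presenceMatrix(sim$grid)
  for (s in sample(speciesNames(sim$grid), 10)) {
    expect_true(all(sim$observedLat[[s]] %in% lat[P[, s] > 0]))
  }
})

test_that("the toy fixture itself is internally consistent", {
  fx <- makeToyFixture()
  expect_invisible(validateTimeTree(fx$tree))
  expect_s4_class(fx$grid, "PresenceGrid")
  expect_equal(fx$version, "1")
  expect_equal(sort(fx$cladeMap$species), sort(fx$tree$tip.label))
})
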