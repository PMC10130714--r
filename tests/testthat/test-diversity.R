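test_that("toy fixture indices match the hand-computed values", {
  fx <- makeToyFixture()
  pd <- faithPD(fx$tree, fx$grid)
  expect_equal(unname(pd[c("c1", "c2", "c3")]), c(3, 4, 0))
  pe <- phyloEndemism(fx$tree, fx$grid)
  expect_equal(unname(pe[c("c1", "c2", "c3")]), c(2, 3, 0))
  expect_equal(sum(pe), totalTreeLength(fx$tree))
})

test_that("TILD of a cell holding the whole toy tree is ln 3 + ln 2", {
  fx <- makeToyFixture()
  P <- matrix(1, 1, 3, dimnames = list("c1", c("A", "B", "C")))
  pg <- PresenceGrid(P, data.frame(lat = 10, lon = 76))
  expect_equal(unname(tild(fx$tree, pg)), log(3) + log(2), tolerance = 1e-12)
  # single-species and empty cells score 0
  expect_equal(unname(tild(fx$tree, fx$grid)["c3"]), 0)
})

test_that("PD without the root path zeroes single-species cells", {
  fx <- makeToyFixture()
  pd <- faithPD(fx$tree, fx$grid, includeRootPath = FALSE)
  # c1 = {A,B}: below their MRCA only the two 1-Myr tip branches count;
  # c2 = {A,C}: the MRCA is the root, so every branch on the A-C path counts
  expect_equal(unname(pd[c("c1", "c2", "c3")]), c(2, 4, 0))
})

test_that("faithPD matches an independent root-path walk on random instances", {
  for (seed in 1:10) {
    tree <- randomUltrametricTree(10, seed = seed)
    pg <- randomGrid(tree, nCellsWanted = 5, seed = seed + 100)
    pd <- faithPD(tree, pg)
    P <- presenceMatrix(pg)
    for (i in seq_len(nCells(pg))) {
      sp <- colnames(P)[P[i, ] > 0]
      expect_equal(unname(pd[i]), bruteForcePD(tree, sp), tolerance = 1e-10)
      # and against the induced-subtree route
      if (length(sp) > 0)
        expect_equal(unname(pd[i]), totalTreeLength(inducedSubtree(tree, sp)),
                     tolerance = 1e-10)
    }
  }
})

test_that("phyloEndemism matches brute-force range weighting", {
  for (seed in 1:5) {
    tree <- randomUltrametricTree(8, seed = seed)
    pg <- randomGrid(tree, nCellsWanted = 5, seed = seed + 50)
    expect_equal(unname(phyloEndemism(tree, pg)),
                 bruteForcePE(tree, presenceMatrix(pg)), tolerance = 1e-10)
  }
})

test_that("PE sums to total tree length when every species is gridded", {
  for (seed in 1:20) {
    tree <- randomUltrametricTree(12, seed = seed)
    pg <- randomGrid(tree, nCellsWanted = 7, seed = seed + 500)
    expect_lt(abs(sum(phyloEndemism(tree, pg)) - totalTreeLength(tree)), 1e-9)
  }
})

test_that("faithPD agrees with picante's implementation", {
  for (seed in 1:5) {
    tree <- randomUltrametricTree(10, seed = seed)
    pg <- randomGrid(tree, nCellsWanted = 6, seed = seed + 30)
    P <- presenceMatrix(pg)
    multi <- rowSums(P) >= 2  # picante's root handling differs for k < 2
    ref <- picante::pd(P[multi, , drop = FALSE], tree, include.root = TRUE)
    expect_equal(unname(faithPD(tree, pg)[multi]), ref$PD, tolerance = 1e-8)
  }
})

test_that("TILD is bounded by rootAge * log(richness) and is >= 0", {
  for (seed in 1:8) {
    tree <- randomUltrametricTree(12, seed = seed)
    pg <- randomGrid(tree, nCellsWanted = 6, seed = seed + 77)
    v <- tild(tree, pg)
    sr <- speciesRichness(pg)
    expect_true(all(v >= 0))
    bound <- rootAge(tree) * log(pmax(sr, 1))
    expect_true(all(v <= bound + 1e-9))
  }
})

test_that("species absent from the tree are a hard error", {
  fx <- makeToyFixture()
  P <- cbind(presenceMatrix(fx$grid), ghost = c(1, 0, 0))
  pg <- PresenceGrid(P, siteCoords(fx$grid))
  expect_error(faithPD(fx$tree, pg), "absent from tree")
  expect_error(faithPD(fx$tree, pg), "ghost")
})

test_that("filterLowRichness keeps exactly the cells at or above minSR", {
  tree <- randomUltrametricTree(20, seed = 2)
  pg <- randomGrid(tree, nCellsWanted = 8, seed = 5, fill = 0.4)
  sr <- speciesRichness(pg)
  flt <- suppressWarnings(suppressMessages(filterLowRichness(pg, minSR = 8)))
  expect_equal(sort(cellIds(flt)), sort(names(sr)[sr >= 8]))
  expect_error(filterLowRichness(pg, minSR = 10000), "below the richness")
})

test_that("clipToObservedLatitudes trims ranges to the observed interval", {
  fx <- makeToyFixture()
  obs <- list(A = 9.5, B = 9.5, C = 10.5)  # A only ever seen at 9.5
  clipped <- clipToObservedLatitudes(fx$grid, obs)
  expect_equal(unname(presenceMatrix(clipped)["c2", "A"]), 0)
  expect_equal(unname(presenceMatrix(clipped)["c1", "A"]), 1)
  expect_error(clipToObservedLatitudes(fx$grid, obs[c("A", "B")]),
               "without observed latitudes")
  # a species losing every presence is dropped with a warning
  expect_warning(clipToObservedLatitudes(fx$grid,
                                         list(A = 9.5, B = 9.5, C = 19)),
                 "lost all presences")
})

test_that("diversityTable assembles all four indices with coordinates", {
  fx <- makeToyFixture()
  tab <- diversityTable(fx$tree, fx$grid)
  expect_equal(names(tab), c("cell", "lat", "lon", "SR", "PD", "PE", "TILD"))
  expect_equal(tab$SR, c(2L, 2L, 0L))
  expect_equal(tab$PD, c(3, 4, 0))
})
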