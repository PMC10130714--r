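test_that("terrainRuggedness matches hand-computed values", {
  e <- rbind(c(0, 10),
             c(20, 30))
  tri <- terrainRuggedness(e)
  # focal (1,1): neighbours 10, 20, 30 -> mean |diff| = (10+20+30)/3 = 20
  expect_equal(tri[1, 1], 20)
  expect_equal(tri[2, 2], 20)  # symmetric corner
  riley <- terrainRuggedness(e, variant = "riley")
  expect_equal(riley[1, 1], sqrt(10^2 + 20^2 + 30^2))
  flat <- terrainRuggedness(matrix(5, 3, 3))
  expect_true(all(flat == 0))
  expect_error(terrainRuggedness(matrix(NA_real_, 2, 2)), "entirely missing")
  expect_error(terrainRuggedness(matrix(1, 1, 5)))
})

test_that("terrainRuggedness propagates missing focal cells and skips missing neighbours", {
  e <- rbind(c(0, 10), c(NA, 30))
  tri <- terrainRuggedness(e)
  expect_true(is.na(tri[2, 1]))
  # focal (1,1): non-missing neighbours 10, 30 -> mean(10, 30) = 20
  expect_equal(tri[1, 1], 20)
})

test_that("aggregateGrid block-averages with partial edge blocks", {
  g <- matrix(1:16, 4, 4, byrow = TRUE)
  a <- aggregateGrid(g, 2)
  expect_equal(dim(a), c(2, 2))
  expect_equal(a[1, 1], mean(c(1, 2, 5, 6)))
  # 3x3 with factor 2: bottom/right blocks are partial
  g2 <- matrix(1:9, 3, 3, byrow = TRUE)
  a2 <- aggregateGrid(g2, 2)
  expect_equal(dim(a2), c(2, 2))
  expect_equal(a2[2, 2], 9)  # single-cell partial block
  expect_equal(aggregateGrid(g, 1), g)
  expect_error(aggregateGrid(g, 5), "larger than the grid")
})

test_that("cwdFromMonthly sums dry-month deficits only", {
  expect_equal(cwdFromMonthly(rep(50, 12)), -600)
  expect_equal(cwdFromMonthly(c(rep(150, 6), rep(40, 6))), -360)
  expect_equal(cwdFromMonthly(rep(200, 12)), 0)  # no dry month
  # monthly ET vector
  expect_equal(cwdFromMonthly(rep(50, 12), et = rep(60, 12)), -120)
  # matrix input: one value per site row
  m <- rbind(rep(50, 12), rep(200, 12))
  expect_equal(cwdFromMonthly(m), c(-600, 0))
  expect_error(cwdFromMonthly(rep(50, 11)), "12")
  expect_error(cwdFromMonthly(rep(-1, 12)), "non-negative")
  expect_error(cwdFromMonthly(rep(50, 12), et = c(1, 2)), "length 1 or 12")
})

test_that("correlateDiversityEnv recovers a known correlation structure", {
  set.seed(31)
  n <- 200
  cwd <- -runif(n, 100, 900)
  sr <- 100 + 0.1 * cwd + rnorm(n, 0, 2)  # strongly positive with CWD
  div <- data.frame(cell = sprintf("c%d", 1:n), SR = sr)
  env <- data.frame(cell = sprintf("c%d", 1:n), CWD = cwd)
  out <- correlateDiversityEnv(div, env)
  expect_equal(nrow(out), 1)
  expect_gt(out$r, 0.9)
  expect_lt(out$p, 1e-6)
  expect_equal(out$n, n)
})

test_that("degenerate correlation pairs are flagged NA, never fabricated", {
  div <- data.frame(cell = c("a", "b", "c", "d"), SR = c(5, 5, 5, 5))
  env <- data.frame(cell = c("a", "b", "c", "d"), CWD = -c(1, 2, 3, 4))
  out <- correlateDiversityEnv(div, env)
  expect_true(is.na(out$r))      # zero variance in SR
  expect_true(is.na(out$p))
  expect_error(correlateDiversityEnv(div[1:2, ], env[1:2, ]),
               "fewer than 3")
  expect_error(correlateDiversityEnv(data.frame(cell = c("a", "b", "c", "d"),
                                                X = 1:4), env),
               "no index")
})

test_that("correlation uses only shared cells, pairwise complete", {
  div <- data.frame(cell = sprintf("c%d", 1:10), SR = 1:10)
  env <- data.frame(cell = sprintf("c%d", 3:12), CWD = -(3:12),
                    MAP = c(NA, 4:12) * 100)
  out <- correlateDiversityEnv(div, env)
  expect_equal(out$n[out$predictor == "CWD"], 8)
  expect_equal(out$n[out$predictor == "MAP"], 7)
  expect_equal(out$r[out$predictor == "CWD"], -1, tolerance = 1e-12)
})
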