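# Environmental layers (terrain ruggedness, climatic water deficit) and
# their correlation with the diversity indices.

#' Topographic ruggedness of an elevation grid
#'
#' Default variant ("mean"): the mean absolute elevation difference between
#' a focal cell and its up-to-8 neighbours; edge cells average over the
#' neighbours they have. The classical sum-of-squares variant ("riley",
#' sqrt of summed squared differences) is offered as an alternative.
#' Missing focal cells stay missing; missing neighbours are skipped.
#'
#' @param elev numeric matrix of elevations (m), at least 2 x 2.
#' @param variant "mean" (default) or "riley".
#' @return matrix of the same shape with TRI values (m), all >= 0.
#' @export
terrainRuggedness <- function(elev, variant = c("mean", "riley")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(elev), nrow(elev) >= 2, ncol(elev) >= 2)
  if (all(is.na(elev))) stop("elevation grid is entirely missing")
  nr <- nrow(elev); nc <- ncol(elev)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(elev[i, j])) next
    ni <- max(1, i - 1):min(nr, i + 1)
    nj <- max(1, j - 1):min(nc, j + 1)
    nb <- as.vector(elev[ni, nj])
    nb <- nb[!is.na(nb)]
    d <- abs(nb - elev[i, j])
    d <- d[-which(d == 0)[1]]  # the block contains the focal cell itself
    out[i, j] <- if (length(d) == 0) 0 else switch(variant,
      mean  = mean(d),
      riley = sqrt(sum(d^2)))
  }
  out
}

#' Aggregate a grid to a coarser resolution by block averaging
#'
#' @param grid numeric matrix.
#' @param factor integer block size; blocks of `factor` x `factor` cells are
#'   averaged. Partial blocks at the right/bottom edges are averaged over
#'   the cells they contain. Missing cells are excluded from their block's
#'   mean.
#' @param method currently only "mean".
#' @return the aggregated matrix, ceiling(nrow/factor) x ceiling(ncol/factor).
#' @export
aggregateGrid <- function(grid, factor, method = "mean") {
  stopifnot(is.matrix(grid), factor >= 1, method == "mean")
  factor <- as.integer(factor)
  if (factor > max(nrow(grid), ncol(grid)))
    stop("aggregation factor larger than the grid")
  if (factor == 1L) return(grid)
  ri <- ceiling(seq_len(nrow(grid)) / factor)
  ci <- ceiling(seq_len(ncol(grid)) / factor)
  out <- matrix(NA_real_, max(ri), max(ci))
  for (a in seq_len(max(ri))) for (b in seq_len(max(ci))) {
    block <- grid[ri == a, ci == b]
    out[a, b] <- mean(block, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Climatic water deficit from monthly climate
#'
#' CWD is the annual sum, over dry months only, of precipitation minus
#' evapotranspiration (mm/yr). A month is dry when precipitation falls
#' short of evapotranspiration; wet-month surpluses are ignored, so CWD is
#' always <= 0, with more negative values meaning stronger seasonal
#' drought.
#'
#' @param precip numeric vector of 12 monthly precipitation totals (mm), or
#'   a matrix with 12 columns (one row per site).
#' @param et monthly evapotranspiration: a single constant (default 100 mm,
#'   the usual fixed-ET convention) or a vector of 12 monthly values.
#' @return CWD in mm/yr (scalar, or one value per row of `precip`).
#' @examples
#' cwdFromMonthly(rep(50, 12))               # -600
#' cwdFromMonthly(c(rep(150, 6), rep(40, 6)))  # -360
#' @export
cwdFromMonthly <- function(precip, et = 100) {
  if (is.matrix(precip)) {
    if (ncol(precip) != 12) stop("precip matrix must have 12 monthly columns")
    return(apply(precip, 1, cwdFromMonthly, et = et))
  }
  if (length(precip) != 12) stop("need 12 monthly precipitation values")
  if (any(precip < 0)) stop("precipitation must be non-negative")
  if (length(et) == 1) et <- rep(et, 12)
  if (length(et) != 12) stop("et must be length 1 or 12")
  sum(pmin(precip - et, 0))
}

#' Correlate diversity indices with environmental predictors
#'
#' Pearson correlation (two-sided test) of each diversity index with each
#' environmental predictor over the grid cells shared by the two tables,
#' using pairwise-complete observations. No spatial autocorrelation
#' correction is applied; treat the p-values as descriptive.
#'
#' @param div data.frame with a `cell` column and index columns (any of SR,
#'   PD, PE, TILD present are used).
#' @param env data.frame with a `cell` column and predictor columns (any of
#'   CWD, MAP, TRI present are used).
#' @param indices,predictors optional character vectors overriding which
#'   columns are correlated.
#' @return data.frame with columns index, predictor, n, r, p. Pairs with
#'   fewer than 3 complete cells or zero variance get NA (flagged, never
#'   fabricated).
#' @export
correlateDiversityEnv <- function(div, env,
                                  indices = intersect(c("SR", "PD", "PE", "TILD"), names(div)),
                                  predictors = intersect(c("CWD", "MAP", "TRI"), names(env))) {
  stopifnot("cell" %in% names(div), "cell" %in% names(env))
  m <- merge(div, env, by = "cell")
  if (nrow(m) < 3) stop("fewer than 3 shared cells between tables")
  if (length(indices) == 0 || length(predictors) == 0)
    stop("no index/predictor columns to correlate")
  grid <- expand.grid(index = indices, predictor = predictors,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    x <- m[[grid$index[k]]]; y <- m[[grid$predictor[k]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(index = grid$index[k], predictor = grid$predictor[k],
                        n = n, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(index = grid$index[k], predictor = grid$predictor[k],
               n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}
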