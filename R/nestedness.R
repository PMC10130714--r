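# Leibold-Mikkelson turnover along the latitudinal gradient, tested against
# a fixed-row-sums (r1) resampling null at every evolutionary depth.

#' Fill embedded absences in an ordered presence matrix
#'
#' Makes every column contiguous over the ordered sites: gaps between a
#' column's first and last presence are filled with presences ("coherent"
#' ranges). Applied before counting replacements so that turnover reflects
#' range replacement rather than holes inside ranges.
#'
#' @param mat binary sites x species matrix, rows in gradient order.
#' @return the filled matrix.
#' @export
fillEmbeddedAbsences <- function(mat) {
  for (j in seq_len(ncol(mat))) {
    idx <- which(mat[, j] > 0)
    if (length(idx) > 1) mat[idx[1]:idx[length(idx)], j] <- 1
  }
  mat
}

#' Observed turnover (lineage replacements) of an ordered matrix
#'
#' Counts, over all pairs of lineages and all pairs of sites (bins), the
#' combinations in which lineage i is present and j absent at one site and
#' the reverse holds at the other — i.e. the number of times one lineage
#' replaces another along the gradient. For a perfectly nested matrix the
#' count is exactly 0. With `adjacentOnly = TRUE` only consecutive site
#' pairs are scanned.
#'
#' @param mat binary sites x lineages matrix, rows ordered along the
#'   gradient (south to north).
#' @param fillEmbedded fill embedded absences first (default TRUE), see
#'   [fillEmbeddedAbsences()].
#' @param adjacentOnly count replacements between consecutive sites only
#'   (default FALSE: all site pairs).
#' @return a single non-negative count.
#' @examples
#' m <- rbind(c(1, 0), c(0, 1))        # checkerboard: one replacement
#' turnoverObserved(m)
#' n <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))  # nested: zero
#' turnoverObserved(n)
#' @export
turnoverObserved <- function(mat, fillEmbedded = TRUE, adjacentOnly = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 2)
  mat <- (mat > 0) * 1
  if (all(mat == 1)) {
    message("turnoverObserved: matrix is saturated (all presences); turnover is 0")
    return(0)
  }
  if (fillEmbedded) mat <- fillEmbeddedAbsences(mat)
  if (adjacentOnly) {
    tot <- 0
    for (k in seq_len(nrow(mat) - 1)) {
      a <- mat[k, ]; b <- mat[k + 1, ]
      tot <- tot + sum(a == 1 & b == 0) * sum(a == 0 & b == 1)
    }
    return(tot)
  }
  D <- t(mat) %*% (1 - mat)  # D[i, j] = sites with i present, j absent
  sum(D * t(D)) / 2
}

# one r1 draw: every site keeps its observed richness and fills it with
# distinct lineages sampled with probability proportional to the observed
# column totals
.r1Sample <- function(richness, weights) {
  ncolm <- length(weights)
  out <- matrix(0, length(richness), ncolm)
  for (r in seq_along(richness)) {
    k <- richness[r]
    if (k == ncolm) out[r, ] <- 1
    else if (k > 0) out[r, sample.int(ncolm, k, prob = weights)] <- 1
  }
  out
}

#' Null distribution of turnover under the r1 model
#'
#' The r1 null holds every site's lineage richness fixed (row sums are
#' preserved exactly) and refills each site with distinct lineages drawn
#' with probability proportional to the lineages' observed occurrence
#' frequencies (column marginals). Turnover is recomputed on every
#' replicate with the same fill/adjacency settings as the observed value.
#'
#' @inheritParams turnoverObserved
#' @param replicates number of null matrices (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of `replicates` null turnover values.
#' @export
r1Null <- function(mat, replicates = 1000, seed = NULL,
                   fillEmbedded = TRUE, adjacentOnly = FALSE) {
  stopifnot(replicates >= 1)
  mat <- (mat > 0) * 1
  richness <- rowSums(mat)
  if (any(richness > ncol(mat)))
    stop("a site is richer than the number of lineages; impossible matrix")
  weights <- colSums(mat)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(replicates), function(i) {
    turnoverObserved(.r1Sample(richness, weights),
                     fillEmbedded = fillEmbedded, adjacentOnly = adjacentOnly)
  }, numeric(1))
}

#' Nestedness test across evolutionary depths
#'
#' For each depth, slices the tree, builds the latitudinally ordered
#' lineage-by-bin matrix, and compares observed turnover with its r1 null
#' distribution. Observed values below the null mean indicate nestedness
#' (species-poor bins hold subsets of richer bins' lineages); above, true
#' turnover. The one-sided empirical p for the nestedness direction is
#' (#\{null <= observed\} + 1) / (replicates + 1); a z-score with a
#' two-sided normal p is reported alongside. Depths where fewer than two
#' lineages occur are flagged untestable rather than scored.
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param pg a [PresenceGrid-class].
#' @param depths depths in Myr; default every 10 Myr from 10 up to the root
#'   age, with the root age itself appended.
#' @param binWidth latitudinal bin width in degrees (default 1).
#' @param replicates null replicates per depth (default 1000).
#' @param seed top-level seed; per-depth child seeds are derived from it
#'   deterministically and recorded in the output.
#' @param fillEmbedded passed to [turnoverObserved()] (default TRUE).
#' @param adjacentOnly passed to [turnoverObserved()] (default FALSE).
#' @param alpha significance level for the verdict column (default 0.05).
#' @return data.frame with one row per depth: age, nLineages, observed,
#'   nullMean, nullSd, z, pEmpirical, pNormal, verdict ("nested",
#'   "turnover", "indeterminate" or "untestable"), replicates, childSeed.
#' @export
nestednessTest <- function(tree, pg, depths = NULL, binWidth = 1,
                           replicates = 1000, seed = 1,
                           fillEmbedded = TRUE, adjacentOnly = FALSE,
                           alpha = 0.05) {
  T <- rootAge(tree)
  if (is.null(depths)) {
    depths <- seq(10, T, by = 10)
    if (length(depths) == 0 || max(depths) < T - 1e-9)
      depths <- c(depths, T)
  }
  binned <- binByLatitude(pg, width = binWidth)
  set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, length(depths))
  rows <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    t <- depths[i]
    blm <- lineagePresenceAtDepth(tree, binned, t)
    if (ncol(blm) < 2) {
      rows[[i]] <- data.frame(age = t, nLineages = ncol(blm), observed = NA,
                              nullMean = NA, nullSd = NA, z = NA,
                              pEmpirical = NA, pNormal = NA,
                              verdict = "untestable",
                              replicates = replicates, childSeed = childSeeds[i])
      next
    }
    obs <- turnoverObserved(blm, fillEmbedded = fillEmbedded,
                            adjacentOnly = adjacentOnly)
    null <- r1Null(blm, replicates = replicates, seed = childSeeds[i],
                   fillEmbedded = fillEmbedded, adjacentOnly = adjacentOnly)
    m <- mean(null); s <- stats::sd(null)
    z <- if (s > 0) (obs - m) / s else NA_real_
    pLow <- (sum(null <= obs) + 1) / (replicates + 1)
    pHigh <- (sum(null >= obs) + 1) / (replicates + 1)
    verdict <- if (obs < m && pLow < alpha) "nested"
               else if (obs > m && pHigh < alpha) "turnover"
               else "indeterminate"
    rows[[i]] <- data.frame(age = t, nLineages = ncol(blm), observed = obs,
                            nullMean = m, nullSd = s, z = z,
                            pEmpirical = pLow,
                            pNormal = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                            verdict = verdict,
                            replicates = replicates, childSeed = childSeeds[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
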