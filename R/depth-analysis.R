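# Latitudinal binning and per-depth lineage summaries.

#' Collapse a presence grid into latitudinal bins
#'
#' A species is present in a bin iff it is present in at least one cell
#' whose centroid latitude falls in [bin lower, bin upper) — half-open, so a
#' centroid sitting exactly on a bin edge belongs to the bin above. Bins are
#' ordered south to north; empty bins (no cells) are dropped.
#'
#' @param pg a [PresenceGrid-class].
#' @param width bin width in degrees (default 1).
#' @return binary matrix, bins x species, rows ordered south to north, with
#'   attributes `lower` and `mid` giving each bin's lower edge and midpoint
#'   latitude.
#' @export
binByLatitude <- function(pg, width = 1) {
  if (nCells(pg) == 0) stop("empty grid: no cells to bin")
  lat <- latitudes(pg)
  lower <- floor(lat / width) * width
  edges <- sort(unique(lower))
  M <- matrix(0, length(edges), nSpecies(pg),
              dimnames = list(sprintf("[%g,%g)", edges, edges + width),
                              speciesNames(pg)))
  P <- presenceMatrix(pg)
  for (k in seq_along(edges)) {
    rows <- which(lower == edges[k])
    M[k, ] <- as.numeric(colSums(P[rows, , drop = FALSE]) > 0)
  }
  attr(M, "lower") <- edges
  attr(M, "mid") <- edges + width / 2
  M
}

#' Lineage presence-absence by latitudinal bin at one evolutionary depth
#'
#' Slices the tree at depth `t` and marks a lineage present in a bin iff any
#' of its descendant species is present there. Lineages with no descendant
#' in the binned matrix are dropped, so every returned column has at least
#' one presence. At t = 0 this recovers the species-level binned matrix
#' (up to column names).
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param binned bins x species matrix from [binByLatitude()].
#' @param t evolutionary depth in Myr.
#' @return binary matrix, bins x lineages, same row order as `binned`, with
#'   attribute `depth`. Column names identify the crossing branch.
#' @export
lineagePresenceAtDepth <- function(tree, binned, t) {
  sl <- sliceLineages(tree, t)
  sp <- colnames(binned)
  cols <- lapply(lineageTips(sl), function(tp) {
    hit <- intersect(tp, sp)
    if (length(hit) == 0) return(NULL)
    as.numeric(rowSums(binned[, hit, drop = FALSE]) > 0)
  })
  keep <- !vapply(cols, is.null, logical(1))
  out <- do.call(cbind, cols[keep])
  if (is.null(out)) stop("no lineage has descendants in the binned matrix")
  dimnames(out) <- list(rownames(binned),
                        sprintf("L%d", sl@lineages$edge[keep]))
  out <- out[, colSums(out) > 0, drop = FALSE]
  attr(out, "lower") <- attr(binned, "lower")
  attr(out, "mid") <- attr(binned, "mid")
  attr(out, "depth") <- t
  out
}

#' Latitudinal range of every lineage at one evolutionary depth
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param pg a [PresenceGrid-class].
#' @param t evolutionary depth in Myr.
#' @return data.frame with one row per lineage occupying at least one cell:
#'   lineage id, minLat, maxLat (over centroids of occupied cells), and
#'   nSpecies (descendants present in the grid).
#' @export
lineageLatitudinalRanges <- function(tree, pg, t) {
  sl <- sliceLineages(tree, t)
  P <- presenceMatrix(pg)
  lat <- latitudes(pg)
  rows <- lapply(seq_len(lineageCount(sl)), function(k) {
    hit <- intersect(lineageTips(sl)[[k]], colnames(P))
    if (length(hit) == 0) return(NULL)
    occ <- rowSums(P[, hit, drop = FALSE]) > 0
    if (!any(occ)) return(NULL)
    data.frame(lineage = sprintf("L%d", sl@lineages$edge[k]),
               minLat = min(lat[occ]), maxLat = max(lat[occ]),
               nSpecies = length(hit))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no lineage occupies any cell at depth ", t)
  rownames(out) <- NULL
  out
}

#' Count lineages restricted south or north of a threshold latitude
#'
#' A lineage is south-restricted iff the centroid latitude of every cell it
#' occupies is <= `threshold`, and north-restricted iff every occupied cell
#' lies strictly above it. Totals count lineages with at least one occupied
#' cell.
#'
#' @inheritParams lineageLatitudinalRanges
#' @param threshold dividing latitude in degrees N (default 13).
#' @return one-row data.frame: age, total, south, north.
#' @export
countRestricted <- function(tree, pg, t, threshold = 13) {
  rg <- lineageLatitudinalRanges(tree, pg, t)
  data.frame(age = t,
             total = nrow(rg),
             south = sum(rg$maxLat <= threshold),
             north = sum(rg$minLat > threshold))
}

#' Shares and ratio of latitudinally restricted lineages
#'
#' Worked arithmetic on a restricted-lineage count table: the percentage of
#' all lineages at each depth confined to the southern (and northern) side
#' of the dividing latitude, and the south:north ratio of restricted
#' lineage richness.
#'
#' @param counts data.frame with columns age, total, south, north, one row
#'   per evolutionary depth (as produced by [countRestricted()]).
#' @return the input with added columns southPct, northPct and
#'   southNorthRatio (NA where no lineage is north-restricted).
#' @export
restrictedShare <- function(counts) {
  stopifnot(all(c("age", "total", "south", "north") %in% names(counts)))
  counts$southPct <- 100 * counts$south / counts$total
  counts$northPct <- 100 * counts$north / counts$total
  counts$southNorthRatio <- ifelse(counts$north > 0,
                                   counts$south / counts$north, NA_real_)
  counts
}
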