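# Per-cell richness-dimension diversity indices: SR, PD, PE, TILD.

# Align a presence grid with a tree: hard error on species missing from the
# tree (silent drops would corrupt provenance), returns the edge-by-cell
# presence machinery shared by PD, PE and TILD.
.alignTree <- function(tree, pg) {
  sp <- speciesNames(pg)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("species in presence matrix but absent from tree: ",
         paste(missing, collapse = ", "))
  etm <- .edgeTipMatrix(tree)
  P <- presenceMatrix(pg)
  # cells x edges: number of descendant species of each edge present per cell
  counts <- P %*% t(etm[, sp, drop = FALSE])
  list(P = P, etm = etm, counts = counts, present = counts > 0,
       bt = branchTable(tree))
}

#' Species richness per grid cell
#'
#' @param pg a [PresenceGrid-class].
#' @return named integer vector, one count per cell.
#' @export
speciesRichness <- function(pg) {
  sr <- rowSums(presenceMatrix(pg))
  stats::setNames(as.integer(sr), cellIds(pg))
}

#' Faith's phylogenetic diversity per grid cell
#'
#' PD is the summed branch length of the subtree spanned by the species in a
#' cell. By default the subtree includes the path to the global root
#' (`includeRootPath = TRUE`), so a single-species cell scores that tip's
#' distance to the root; with `includeRootPath = FALSE` only branches of the
#' minimal spanning subtree below the cell's MRCA are counted (a
#' single-species cell then scores 0). Empty cells score 0 either way.
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param pg a [PresenceGrid-class]; all species must be tips of `tree`.
#' @param includeRootPath logical, see above.
#' @return named numeric vector of PD values (Myr), one per cell.
#' @examples
#' fx <- makeToyFixture()
#' faithPD(fx$tree, fx$grid)
#' @export
faithPD <- function(tree, pg, includeRootPath = TRUE) {
  al <- .alignTree(tree, pg)
  use <- al$present
  if (!includeRootPath) {
    sr <- rowSums(al$P)
    # drop edges at-or-above the cell MRCA: those whose descendant set
    # contains every species of the cell
    use <- use & (al$counts < sr)
  }
  pd <- as.numeric(use %*% al$bt$length)
  stats::setNames(pd, cellIds(pg))
}

#' Phylogenetic endemism per grid cell
#'
#' Each branch's length is divided by its range: the number of grid cells
#' occupied by at least one of its descendant species. A cell's PE is the
#' sum of these range-weighted lengths over all branches represented in the
#' cell. When every species occupies at least one cell, PE summed over all
#' cells equals the total tree length restricted to branches with extant
#' representation in the grid (each branch spreads its length over exactly
#' its range).
#'
#' @inheritParams faithPD
#' @return named numeric vector of PE values (Myr), one per cell.
#' @export
phyloEndemism <- function(tree, pg) {
  al <- .alignTree(tree, pg)
  rng <- colSums(al$present)
  w <- ifelse(rng > 0, al$bt$length / pmax(rng, 1), 0)
  pe <- as.numeric(al$present %*% w)
  stats::setNames(pe, cellIds(pg))
}

#' Time-integrated lineage diversity per grid cell
#'
#' TILD(cell) = integral over [0, T] of ln n(t) dt, where n(t) is the number
#' of branches of the cell's induced (root-anchored) subtree crossing depth
#' t and T is the global root age. The integral is computed exactly as a sum
#' over inter-node intervals (width x ln count); intervals where a single
#' lineage survives contribute nothing, so integrating to the global root
#' age rather than the cell subtree's own crown does not change the value,
#' it only puts all cells on one time axis. Cells with one species (or none)
#' score 0.
#'
#' @inheritParams faithPD
#' @return named numeric vector of TILD values, one per cell.
#' @examples
#' fx <- makeToyFixture()
#' tild(fx$tree, fx$grid)  # cell with all of A,B,C scores ln 3 + ln 2
#' @export
tild <- function(tree, pg) {
  al <- .alignTree(tree, pg)
  T <- rootAge(tree)
  out <- numeric(nCells(pg))
  for (i in seq_len(nCells(pg))) {
    idx <- which(al$present[i, ])
    if (length(idx) < 2) next
    lo <- al$bt$childAge[idx]
    hi <- al$bt$parentAge[idx]
    br <- sort(unique(c(0, lo, hi, T)))
    br <- br[br <= T + 1e-12]
    mids <- (br[-1] + br[-length(br)]) / 2
    n <- vapply(mids, function(m) sum(lo <= m & hi > m), numeric(1))
    n[n < 1] <- 1  # above the subtree crown only the root path survives
    out[i] <- sum(diff(br) * log(n))
  }
  stats::setNames(out, cellIds(pg))
}

#' Per-cell diversity table (SR, PD, PE, TILD)
#'
#' @inheritParams faithPD
#' @return data.frame with columns cell, lat, lon, SR, PD, PE, TILD.
#' @export
diversityTable <- function(tree, pg, includeRootPath = TRUE) {
  co <- siteCoords(pg)
  data.frame(
    cell = cellIds(pg),
    lat  = co$lat,
    lon  = co$lon,
    SR   = speciesRichness(pg),
    PD   = faithPD(tree, pg, includeRootPath = includeRootPath),
    PE   = phyloEndemism(tree, pg),
    TILD = tild(tree, pg),
    row.names = NULL
  )
}

#' Drop species-poor grid cells
#'
#' Retains exactly the cells with at least `minSR` species, the
#' conservative-estimate filter used before computing diversity indices.
#' Species that lose all their presences are dropped with a warning (via the
#' subset method), keeping the range definition of PE valid.
#'
#' @param pg a [PresenceGrid-class].
#' @param minSR minimum species richness for a cell to be kept (default 10).
#' @return the filtered [PresenceGrid-class].
#' @export
filterLowRichness <- function(pg, minSR = 10) {
  sr <- speciesRichness(pg)
  keep <- which(sr >= minSR)
  if (length(keep) == 0)
    stop("all ", nCells(pg), " cells fall below the richness threshold ", minSR)
  dropped <- nCells(pg) - length(keep)
  if (dropped > 0)
    message("filterLowRichness: removed ", dropped, " of ", nCells(pg),
            " cells with fewer than ", minSR, " species")
  pg[keep, ]
}

#' Clip species ranges to their observed latitudinal extent
#'
#' For each species, presences in cells whose centroid latitude falls
#' outside the closed interval [min, max] of that species' observed
#' occurrence latitudes are removed — the conservative range-clipping step
#' applied to model-predicted distributions.
#'
#' @param pg a [PresenceGrid-class].
#' @param observedLat named list (or list-like) mapping each species to a
#'   numeric vector of observed occurrence latitudes; every species in `pg`
#'   must have at least one observation.
#' @return the clipped [PresenceGrid-class].
#' @export
clipToObservedLatitudes <- function(pg, observedLat) {
  sp <- speciesNames(pg)
  missing <- setdiff(sp, names(observedLat))
  bad <- sp[sp %in% names(observedLat) &
            vapply(observedLat[intersect(sp, names(observedLat))],
                   function(v) length(v) == 0 || all(is.na(v)), logical(1))]
  if (length(missing) || length(bad))
    stop("species without observed latitudes: ",
         paste(c(missing, bad), collapse = ", "))
  P <- presenceMatrix(pg)
  lat <- latitudes(pg)
  for (s in sp) {
    r <- range(observedLat[[s]], na.rm = TRUE)
    outside <- lat < r[1] | lat > r[2]
    P[outside, s] <- 0
  }
  empty <- colSums(P) == 0
  if (any(empty)) {
    warning(sum(empty), " species lost all presences after clipping and were dropped: ",
            paste(utils::head(sp[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "")
    P <- P[, !empty, drop = FALSE]
  }
  PresenceGrid(P, siteCoords(pg), resKm = pg@resKm)
}
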