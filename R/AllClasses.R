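#' @import methods
NULL

#' Gridded presence-absence data bound to site coordinates
#'
#' `PresenceGrid` is the central data container of the package: a binary
#' cells-by-species matrix together with the centroid coordinates of every
#' grid cell. Rows are grid cells (identified by `rownames`), columns are
#' species. Cells may be empty, but every species must occur in at least one
#' cell, so that range sizes used by phylogenetic endemism are well defined.
#'
#' @slot presence integer matrix of 0/1 entries, cells x species, with unique
#'   row (cell id) and column (species) names.
#' @slot coords data.frame with one row per cell (same order as `presence`)
#'   and numeric columns `lat` and `lon` in decimal degrees.
#' @slot resKm nominal grid resolution in kilometres (metadata only).
#'
#' @seealso [PresenceGrid()] for the validating constructor,
#'   [presenceMatrix()], [siteCoords()], [latitudes()] for accessors.
#' @export
setClass("PresenceGrid",
  representation(
    presence = "matrix",
    coords   = "data.frame",
    resKm    = "numeric"
  )
)

setValidity("PresenceGrid", function(object) {
  p <- object@presence
  msgs <- character()
  if (!is.numeric(p)) msgs <- c(msgs, "presence matrix must be numeric 0/1")
  if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
    msgs <- c(msgs, "cell ids (rownames) must be present and unique")
  if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
    msgs <- c(msgs, "species names (colnames) must be present and unique")
  if (is.numeric(p) && length(p) && !all(p %in% c(0, 1)))
    msgs <- c(msgs, "presence entries must be 0 or 1")
  if (ncol(p) > 0 && any(colSums(p) == 0))
    msgs <- c(msgs, sprintf(
      "species with no presences: %s",
      paste(colnames(p)[colSums(p) == 0], collapse = ", ")))
  if (!all(c("lat", "lon") %in% names(object@coords)))
    msgs <- c(msgs, "coords must have 'lat' and 'lon' columns")
  if (nrow(object@coords) != nrow(p))
    msgs <- c(msgs, "coords must have one row per grid cell")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PresenceGrid
#'
#' @param presence matrix (or data.frame) of 0/1 presences, cells x species.
#'   Row names are cell ids, column names species.
#' @param coords data.frame with columns `lat` and `lon` (decimal degrees),
#'   either with rownames matching the cell ids or in matrix row order.
#' @param resKm nominal cell size in km (default 10, metadata only).
#' @return a validated [PresenceGrid-class] object.
#' @examples
#' fx <- makeToyFixture()
#' fx$grid
#' @export
PresenceGrid <- function(presence, coords, resKm = 10) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "double"
  coords <- as.data.frame(coords)
  if (!is.null(rownames(coords)) &&
      !identical(rownames(coords), as.character(seq_len(nrow(coords))))) {
    missing <- setdiff(rownames(presence), rownames(coords))
    if (length(missing))
      stop("cells missing from coords: ", paste(missing, collapse = ", "))
    coords <- coords[rownames(presence), , drop = FALSE]
  }
  new("PresenceGrid", presence = presence, coords = coords, resKm = resKm)
}

#' Branches of a phylogeny crossing one evolutionary depth
#'
#' A `LineageSlice` holds the set of branches of an ultrametric tree that
#' cross a given depth t (measured backward from the present, in Myr), each
#' with the ages of its end nodes and the set of extant species descending
#' from it. At a given depth the descendant tip sets of distinct lineages are
#' disjoint and jointly cover all tips.
#'
#' @slot depth the slicing depth t in Myr.
#' @slot lineages data.frame with columns `edge` (index into the tree's edge
#'   matrix), `parentAge`, `childAge` (Myr) and `nTips`.
#' @slot tips list of character vectors, one per lineage, the descendant
#'   species of that lineage.
#' @export
setClass("LineageSlice",
  representation(
    depth    = "numeric",
    lineages = "data.frame",
    tips     = "list"
  )
)

setValidity("LineageSlice", function(object) {
  if (nrow(object@lineages) != length(object@tips))
    return("lineage table and tip list lengths differ")
  alltips <- unlist(object@tips)
  if (anyDuplicated(alltips))
    return("descendant tip sets of distinct lineages must be disjoint")
  TRUE
})
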