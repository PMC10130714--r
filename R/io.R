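# Plain-CSV interchange for presence matrices, site grids, environment
# tables and clade maps.

#' Read a presence matrix and site grid from CSV
#'
#' The wide dialect has one row per cell: first column the cell id, the
#' remaining columns one 0/1 column per species. The sparse triplet dialect
#' has columns `cell` and `species` (plus an optional `presence` column of
#' 0/1), one row per occupied cell-species pair; it is detected by its
#' header.
#'
#' @param presencePath CSV with the presence data (either dialect).
#' @param gridPath CSV with columns cell, lat, lon.
#' @param resKm nominal resolution in km (default 10).
#' @return a [PresenceGrid-class].
#' @export
readPresenceGrid <- function(presencePath, gridPath, resKm = 10) {
  grid <- utils::read.csv(gridPath, stringsAsFactors = FALSE)
  stopifnot(all(c("cell", "lat", "lon") %in% names(grid)))
  if (anyDuplicated(grid$cell)) stop("duplicate cell ids in ", gridPath)
  pres <- utils::read.csv(presencePath, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (all(c("cell", "species") %in% names(pres))) {
    val <- if ("presence" %in% names(pres)) pres$presence else 1
    pres <- pres[val > 0, c("cell", "species")]
    cells <- as.character(grid$cell)
    species <- sort(unique(pres$species))
    P <- matrix(0, length(cells), length(species),
                dimnames = list(cells, species))
    P[cbind(match(pres$cell, cells), match(pres$species, species))] <- 1
  } else {
    P <- as.matrix(pres[, -1, drop = FALSE])
    rownames(P) <- as.character(pres[[1]])
    P <- P[match(as.character(grid$cell), rownames(P)), , drop = FALSE]
  }
  PresenceGrid(P, data.frame(lat = grid$lat, lon = grid$lon,
                             row.names = as.character(grid$cell)),
               resKm = resKm)
}

#' Write a presence grid to CSV (wide dialect plus site grid)
#'
#' @param pg a [PresenceGrid-class].
#' @param presencePath,gridPath output CSV paths.
#' @export
writePresenceGrid <- function(pg, presencePath, gridPath) {
  P <- presenceMatrix(pg)
  utils::write.csv(data.frame(cell = rownames(P), P, check.names = FALSE),
                   presencePath, row.names = FALSE)
  co <- siteCoords(pg)
  utils::write.csv(data.frame(cell = rownames(co), lat = co$lat, lon = co$lon),
                   gridPath, row.names = FALSE)
  invisible(c(presencePath, gridPath))
}

#' Read a per-cell environment table
#'
#' @param path CSV with columns cell, CWD, MAP, TRI (extra columns kept).
#' @return data.frame; basic sign sanity checks are applied (CWD <= 0,
#'   TRI >= 0).
#' @export
readEnvTable <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("cell" %in% names(env))
  if ("CWD" %in% names(env) && any(env$CWD > 0, na.rm = TRUE))
    stop("CWD must be <= 0 (mm/yr of dry-season deficit)")
  if ("TRI" %in% names(env) && any(env$TRI < 0, na.rm = TRUE))
    stop("TRI must be >= 0")
  env
}

#' Read a clade map
#'
#' @param path CSV with columns species, family, superorder.
#' @return data.frame.
#' @export
readCladeMap <- function(path) {
  cm <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "family", "superorder") %in% names(cm)))
  cm
}

#' Read per-species observed occurrence latitudes
#'
#' @param path CSV with columns species, lat (one row per occurrence).
#' @return named list of numeric latitude vectors.
#' @export
readObservedLatitudes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "lat") %in% names(d)))
  split(d$lat, d$species)
}
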