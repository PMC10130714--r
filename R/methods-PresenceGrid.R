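#' @rdname PresenceGrid-class
#' @aliases presenceMatrix,PresenceGrid-method
setMethod("presenceMatrix", "PresenceGrid", function(x) x@presence)

#' @rdname PresenceGrid-class
setMethod("siteCoords", "PresenceGrid", function(x) {
  out <- x@coords
  rownames(out) <- rownames(x@presence)
  out
})

#' @rdname PresenceGrid-class
setMethod("latitudes", "PresenceGrid", function(x) {
  stats::setNames(x@coords$lat, rownames(x@presence))
})

#' @rdname PresenceGrid-class
setMethod("cellIds", "PresenceGrid", function(x) rownames(x@presence))

#' @rdname PresenceGrid-class
setMethod("speciesNames", "PresenceGrid", function(x) colnames(x@presence))

#' @rdname PresenceGrid-class
setMethod("nCells", "PresenceGrid", function(x) nrow(x@presence))

#' @rdname PresenceGrid-class
setMethod("nSpecies", "PresenceGrid", function(x) ncol(x@presence))

#' Subset a PresenceGrid by cells and/or species
#'
#' Species columns emptied by a cell subset are dropped with a warning, so
#' the result always satisfies the class invariant that every species
#' occupies at least one cell.
#'
#' @param x a `PresenceGrid`
#' @param i cell ids or indices
#' @param j species names or indices
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "PresenceGrid", function(x, i, j, ..., drop = FALSE) {
  p <- x@presence
  co <- x@coords
  if (!missing(i)) {
    if (is.character(i)) i <- match(i, rownames(p))
    p <- p[i, , drop = FALSE]
    co <- co[i, , drop = FALSE]
  }
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, colnames(p))
    p <- p[, j, drop = FALSE]
  }
  empty <- colSums(p) == 0
  if (any(empty)) {
    warning(sum(empty), " species lost all presences in subset and were dropped: ",
            paste(utils::head(colnames(p)[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "")
    p <- p[, !empty, drop = FALSE]
  }
  new("PresenceGrid", presence = p, coords = co, resKm = x@resKm)
})

setMethod("show", "PresenceGrid", function(object) {
  cat("PresenceGrid:", nrow(object@presence), "cells x",
      ncol(object@presence), "species\n")
  cat("  latitude range:",
      paste(sprintf("%.2f", range(object@coords$lat)), collapse = " to "),
      "degN; nominal resolution", object@resKm, "km\n")
  cat("  occupancy:", sum(object@presence), "presences (",
      sprintf("%.1f%%", 100 * mean(object@presence)), "fill )\n")
  invisible(object)
})

#' @rdname LineageSlice-class
setMethod("sliceDepth", "LineageSlice", function(x) x@depth)

#' @rdname LineageSlice-class
setMethod("lineageCount", "LineageSlice", function(x) nrow(x@lineages))

#' @rdname LineageSlice-class
setMethod("lineageTips", "LineageSlice", function(x) x@tips)

setMethod("show", "LineageSlice", function(object) {
  cat("LineageSlice at depth", object@depth, "Myr:",
      nrow(object@lineages), "lineages covering",
      length(unlist(object@tips)), "tips\n")
  invisible(object)
})
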