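#' @rdname PresenceGrid-class
#' @param x a `PresenceGrid`
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname PresenceGrid-class
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))

#' @rdname PresenceGrid-class
#' @export
setGeneric("latitudes", function(x) standardGeneric("latitudes"))

#' @rdname PresenceGrid-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname PresenceGrid-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname PresenceGrid-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname PresenceGrid-class
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname LineageSlice-class
#' @param x a `LineageSlice`
#' @export
setGeneric("sliceDepth", function(x) standardGeneric("sliceDepth"))

#' @rdname LineageSlice-class
#' @export
setGeneric("lineageCount", function(x) standardGeneric("lineageCount"))

#' @rdname LineageSlice-class
#' @export
setGeneric("lineageTips", function(x) standardGeneric("lineageTips"))
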