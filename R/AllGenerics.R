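#' @rdname RasterMap-class
#' @param object,x a package object.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname RasterMap-class
#' @export
setGeneric("cellSizeUm", function(object) standardGeneric("cellSizeUm"))

#' @rdname PcfResult-class
#' @export
setGeneric("pcfTable", function(object) standardGeneric("pcfTable"))

#' @rdname PcfResult-class
#' @export
setGeneric("overallDensity", function(object) standardGeneric("overallDensity"))

#' @rdname CiResult-class
#' @export
setGeneric("classifications", function(object) standardGeneric("classifications"))

#' @rdname CiResult-class
#' @export
setGeneric("ciBounds", function(object) standardGeneric("ciBounds"))
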