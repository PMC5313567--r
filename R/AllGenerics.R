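#' @include AllGenerics.R
NULL

#' Accessors for pbitomo data objects
#'
#' Small family of generics shared by the S4 containers: pixel payloads,
#' geometry, angle lists, detector/rotation-axis bookkeeping.
#'
#' @param x an object.
#' @param object an object.
#' @param value replacement value.
#' @name pbitomo-accessors
NULL

#' @rdname pbitomo-accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("axisPosition", function(x) standardGeneric("axisPosition"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("axisPosition<-", function(x, value) standardGeneric("axisPosition<-"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("energy", function(x) standardGeneric("energy"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("distance", function(x) standardGeneric("distance"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("scanMode", function(x) standardGeneric("scanMode"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("flats", function(x, ...) standardGeneric("flats"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("darks", function(x) standardGeneric("darks"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("nProjections", function(x) standardGeneric("nProjections"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname pbitomo-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
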