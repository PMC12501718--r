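# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname accessors
#' @export
setGeneric("tiTimes", function(x) standardGeneric("tiTimes"))

#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname accessors
#' @export
setGeneric("fiberV1", function(x) standardGeneric("fiberV1"))

#' @rdname accessors
#' @export
setGeneric("fiberFA", function(x) standardGeneric("fiberFA"))

#' @rdname accessors
#' @export
setGeneric("thetaDegrees", function(x) standardGeneric("thetaDegrees"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("t1Map", function(x) standardGeneric("t1Map"))

#' @rdname accessors
#' @export
setGeneric("r1Map", function(x) standardGeneric("r1Map"))

#' @rdname accessors
#' @export
setGeneric("sseMap", function(x) standardGeneric("sseMap"))

#' @rdname accessors
#' @export
setGeneric("polarityBoundaryMap", function(x) standardGeneric("polarityBoundaryMap"))

#' @rdname accessors
#' @export
setGeneric("successMask", function(x) standardGeneric("successMask"))

#' @rdname accessors
#' @export
setGeneric("fitMode", function(x) standardGeneric("fitMode"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("quantityLabel", function(x) standardGeneric("quantityLabel"))

#' Evaluate a ground-truth model at fiber-to-field angles
#'
#' @param model an [AngularT1Model-class] or [TwoPoolModel-class] object.
#' @param theta numeric, fiber-to-field angles in degrees.
#' @return `predictT1`: true T1 in ms at each angle (for a two-pool model,
#'   the long-compartment T1, constant in theta). `shortFraction`: the
#'   short-pool signal fraction at each angle.
#' @examples
#' m <- angularT1Model(t1Parallel = 537, delta090 = 27,
#'                     humpAmplitude = 23.5, humpCenter = 40, humpFwhm = 34)
#' predictT1(m, c(0, 40, 90))
#' @export
setGeneric("predictT1", function(model, theta) standardGeneric("predictT1"))

#' @rdname predictT1
#' @export
setGeneric("shortFraction", function(model, theta) standardGeneric("shortFraction"))
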