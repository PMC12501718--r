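#' Accessors for fiberT1 objects
#'
#' Small accessor functions for the S4 containers: inversion times and
#' protocol of a [TISeries-class]; direction vectors and FA of a
#' [FiberField-class]; angle values and validity of a [ThetaMap-class];
#' fitted maps of a [T1MapResult-class]; bin geometry of an
#' [AngularProfile-class].
#'
#' @param x an object of the matching class.
#' @return The slot contents (arrays, vectors or scalars) as documented for
#'   each class.
#' @name accessors
NULL

#' @rdname accessors
setMethod("tiTimes", "AcquisitionProtocol", function(x) x@tiList)

#' @rdname accessors
setMethod("tiTimes", "TISeries", function(x) x@protocol@tiList)

#' @rdname accessors
setMethod("protocol", "TISeries", function(x) x@protocol)

#' @rdname accessors
setMethod("seriesData", "TISeries", function(x) x@data)

#' @rdname accessors
setMethod("fiberV1", "FiberField", function(x) x@v1)

#' @rdname accessors
setMethod("fiberFA", "FiberField", function(x) x@fa)

#' @rdname accessors
setMethod("thetaDegrees", "ThetaMap", function(x) x@theta)

#' @rdname accessors
setMethod("validMask", "ThetaMap", function(x) x@validMask)

#' @rdname accessors
setMethod("t1Map", "T1MapResult", function(x) x@t1Map)

#' @rdname accessors
setMethod("r1Map", "T1MapResult", function(x) x@r1Map)

#' @rdname accessors
setMethod("sseMap", "T1MapResult", function(x) x@sseMap)

#' @rdname accessors
setMethod("polarityBoundaryMap", "T1MapResult", function(x) x@polarityBoundaryMap)

#' @rdname accessors
setMethod("successMask", "T1MapResult", function(x) x@successMask)

#' @rdname accessors
setMethod("fitMode", "T1MapResult", function(x) x@fitMode)

#' @rdname accessors
setMethod("binCenters", "AngularProfile", function(x) x@binCenters)

#' @rdname accessors
setMethod("binCenters", "Angular2DGrid", function(x) x@binCenters)

#' @rdname accessors
setMethod("binCounts", "AngularProfile", function(x) x@n)

#' @rdname accessors
setMethod("binCounts", "Angular2DGrid", function(x) x@n)

#' @rdname accessors
setMethod("quantityLabel", "AngularProfile", function(x) x@quantityLabel)

#' @rdname accessors
setMethod("quantityLabel", "Angular2DGrid", function(x) x@quantityLabel)

#' @rdname accessors
setMethod("quantityLabel", "AngularFeatureSet", function(x) x@quantityLabel)

#' Coerce an angular profile to a data.frame
#'
#' @param x an [AngularProfile-class].
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return data.frame with columns `bin_center`, `mean`, `sd`, `n`.
#' @export
as.data.frame.AngularProfile <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(bin_center = x@binCenters, mean = x@mean, sd = x@sd,
             n = as.integer(x@n))
}

setMethod("as.data.frame", "AngularProfile", as.data.frame.AngularProfile)

#' Coerce a feature set to a one-row data.frame
#'
#' Columns mirror the quantitative feature table: endpoint difference,
#' hump amplitude / peak / FWHM, mask-wide mean and percent features.
#'
#' @param x an [AngularFeatureSet-class].
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return one-row data.frame.
#' @export
as.data.frame.AngularFeatureSet <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    quantity = x@quantityLabel,
    delta_0_90 = x@delta090,
    pct_delta = x@pctDelta,
    hump_amplitude = x@humpAmplitude,
    pct_hump = x@pctHump,
    peak_angle = x@peakAngle,
    fwhm = x@fwhm,
    fwhm_bounded = x@fwhmBounded,
    mean_value = x@meanValue,
    endpoint_0 = x@endpoint0,
    endpoint_90 = x@endpoint90,
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "AngularFeatureSet", as.data.frame.AngularFeatureSet)

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol '%s': %d TIs [%s] ms, TR %g ms, read flip %g deg\n",
              object@fieldLabel, length(object@tiList),
              paste(object@tiList, collapse = ", "), object@tr,
              object@readFlip))
  cat(sprintf("  B0 direction: (%g, %g, %g)\n", object@b0Direction[1],
              object@b0Direction[2], object@b0Direction[3]))
})

setMethod("show", "TISeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("TISeries: %d x %d x %d voxels, %d inversion times (%s)\n",
              d[1], d[2], d[3], d[4], object@protocol@fieldLabel))
})

setMethod("show", "FiberField", function(object) {
  d <- dim(object@fa)
  cat(sprintf("FiberField: %d x %d x %d voxels, FA range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(object@fa), max(object@fa)))
})

setMethod("show", "ThetaMap", function(object) {
  cat(sprintf("ThetaMap: %s voxels, %d valid\n",
              paste(dim(object@theta), collapse = " x "),
              sum(object@validMask)))
})

setMethod("show", "T1MapResult", function(object) {
  ok <- object@successMask
  cat(sprintf("T1MapResult (mode '%s'): %d / %d voxels fit successfully\n",
              object@fitMode, sum(ok), length(ok)))
  if (any(ok)) {
    cat(sprintf("  T1 median %.1f ms (IQR %.1f-%.1f)\n",
                stats::median(object@t1Map[ok]),
                stats::quantile(object@t1Map[ok], 0.25),
                stats::quantile(object@t1Map[ok], 0.75)))
  }
})

setMethod("show", "AngularProfile", function(object) {
  cat(sprintf("AngularProfile '%s': %d bins of %g deg, %d voxels\n",
              object@quantityLabel, length(object@binCenters),
              object@binWidth, sum(object@n)))
})

setMethod("show", "AngularFeatureSet", function(object) {
  cat(sprintf("AngularFeatureSet '%s':\n", object@quantityLabel))
  cat(sprintf("  delta(0-90): %.2f (%.1f%% of mean %.2f)\n",
              object@delta090, object@pctDelta, object@meanValue))
  cat(sprintf("  hump: %.2f (%.1f%%) at %.1f deg, FWHM %.1f deg%s\n",
              object@humpAmplitude, object@pctHump, object@peakAngle,
              object@fwhm, if (isTRUE(object@fwhmBounded)) "" else " (unbounded)"))
})
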