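#' @import methods
NULL

GAUSS_LOG2_4 <- 4 * log(2)

gaussHump <- function(theta, center, fwhm) {
  exp(-GAUSS_LOG2_4 * (theta - center)^2 / fwhm^2)
}

#' Acquisition protocol for a TI image series
#'
#' Describes the inversion-recovery acquisition that produced (or is to be
#' simulated for) a series of magnitude TI volumes: the ordered inversion
#' times, repetition time, readout flip angle, field label and the direction
#' of the main magnetic field B0 in the voxel grid.
#'
#' @slot fieldLabel character, e.g. `"1.5T"`, `"3T"`, `"7T"` or a custom tag.
#' @slot tiList numeric, strictly increasing inversion times in ms (>= 4).
#' @slot tr numeric, repetition time in ms.
#' @slot readFlip numeric, readout flip angle in degrees.
#' @slot b0Direction numeric length-3 unit vector, direction of B0 in grid
#'   coordinates (defaults to the third grid axis, scanner z).
#' @seealso [acquisitionProtocol()], [protocolPreset()]
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(
    fieldLabel = "character",
    tiList = "numeric",
    tr = "numeric",
    readFlip = "numeric",
    b0Direction = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  ti <- object@tiList
  if (length(ti) < 4L) msg <- c(msg, "tiList must contain at least 4 inversion times")
  if (any(ti <= 0)) msg <- c(msg, "all inversion times must be positive")
  if (any(diff(ti) <= 0)) msg <- c(msg, "tiList must be strictly increasing")
  b0 <- object@b0Direction
  if (length(b0) != 3L) msg <- c(msg, "b0Direction must have length 3")
  else if (abs(sqrt(sum(b0^2)) - 1) > 1e-9) {
    msg <- c(msg, "b0Direction must be a unit vector (|b0| = 1 within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth angular T1 model for the phantom
#'
#' Parameterises the per-voxel true T1 as a function of the fiber-to-field
#' angle theta (degrees):
#' \deqn{T_1(\theta) = T_{1,\parallel} + \Delta_{0\text{-}90}\,\theta/90 +
#'   A\,\exp(-4\ln 2\,(\theta - c)^2 / w^2)}
#' i.e. a linear increase from parallel (0 degrees) to perpendicular
#' (90 degrees) plus a Gaussian hump parameterised directly by its
#' full width at half maximum, so that FWHM recovery by the downstream
#' quantification is analytic.
#'
#' @slot t1Parallel T1 at theta = 0, ms (> 0).
#' @slot delta090 linear increase from 0 to 90 degrees, ms.
#' @slot humpAmplitude Gaussian hump amplitude, ms.
#' @slot humpCenter hump center, degrees in \[0, 90\].
#' @slot humpFwhm hump full width at half maximum, degrees (> 0).
#' @seealso [angularT1Model()], [predictT1()]
#' @exportClass AngularT1Model
setClass("AngularT1Model",
  representation(
    t1Parallel = "numeric",
    delta090 = "numeric",
    humpAmplitude = "numeric",
    humpCenter = "numeric",
    humpFwhm = "numeric"
  )
)

setValidity("AngularT1Model", function(object) {
  msg <- character()
  if (object@t1Parallel <= 0) msg <- c(msg, "t1Parallel must be > 0")
  if (object@humpFwhm <= 0) msg <- c(msg, "humpFwhm must be > 0")
  if (object@humpCenter < 0 || object@humpCenter > 90) {
    msg <- c(msg, "humpCenter must lie in [0, 90] degrees")
  }
  th <- seq(0, 90, by = 0.5)
  t1 <- object@t1Parallel + object@delta090 * th / 90 +
    object@humpAmplitude * gaussHump(th, object@humpCenter, object@humpFwhm)
  if (!all(is.finite(t1)) || any(t1 <= 0)) {
    msg <- c(msg, "T1(theta) must be finite and > 0 on [0, 90] degrees")
  }
  if (length(msg)) msg else TRUE
})

#' Two-pool recovery model for the phantom
#'
#' Voxel signal as a mixture of a fast-relaxing short-T1 compartment
#' (myelin-associated; its T1 is strongly field dependent: roughly 120 ms at
#' 1.5 T, 260 ms at 3 T and 540 ms at 7 T) and a slow long-T1 bulk-water
#' compartment. The short-pool fraction varies with the fiber-to-field angle
#' as baseline + amplitude * Gaussian(center, fwhm); the amplitude may be
#' negative (a dip of the short-pool fraction near the hump center), which is
#' the default emulation because a locally *reduced* fast fraction is what
#' raises the apparent mono-exponential T1 there.
#'
#' @slot t1Short short-compartment T1, ms.
#' @slot t1Long long-compartment T1, ms (> t1Short).
#' @slot fractionShortBaseline short-pool fraction away from the hump,
#'   in \[0, 1).
#' @slot fractionShortHumpAmplitude signed change of the short-pool fraction
#'   at the hump center.
#' @slot humpCenter degrees.
#' @slot humpFwhm degrees (> 0).
#' @seealso [twoPoolModel()], [shortFraction()]
#' @exportClass TwoPoolModel
setClass("TwoPoolModel",
  representation(
    t1Short = "numeric",
    t1Long = "numeric",
    fractionShortBaseline = "numeric",
    fractionShortHumpAmplitude = "numeric",
    humpCenter = "numeric",
    humpFwhm = "numeric"
  )
)

setValidity("TwoPoolModel", function(object) {
  msg <- character()
  if (object@t1Short <= 0) msg <- c(msg, "t1Short must be > 0")
  if (object@t1Short >= object@t1Long) msg <- c(msg, "t1Short must be < t1Long")
  if (object@humpFwhm <= 0) msg <- c(msg, "humpFwhm must be > 0")
  th <- seq(0, 90, by = 0.5)
  f <- object@fractionShortBaseline + object@fractionShortHumpAmplitude *
    gaussHump(th, object@humpCenter, object@humpFwhm)
  if (any(f < 0) || any(f >= 1)) {
    msg <- c(msg, "short-pool fraction must satisfy 0 <= f(theta) < 1 on [0, 90]")
  }
  if (length(msg)) msg else TRUE
})

#' Noise specification for the simulated TI series
#'
#' Magnitude MRI noise is Rician by construction (magnitude of a complex
#' Gaussian); `model = "none"` yields noiseless series and ignores `sigma`.
#'
#' @slot model `"none"` or `"rician"`.
#' @slot sigma per-channel Gaussian standard deviation, signal units (>= 0).
#' @slot seed integer RNG seed (NA = do not touch the RNG state).
#' @seealso [noiseSpec()]
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(model = "character", sigma = "numeric", seed = "integer")
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@model %in% c("none", "rician")) {
    msg <- c(msg, "model must be 'none' or 'rician'")
  }
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-voxel fiber orientation and anisotropy
#'
#' Holds the principal-diffusion-direction unit vector (sign-ambiguous, as
#' produced by a diffusion-tensor fit) and the fractional anisotropy for
#' every voxel of a 3-D grid, co-registered to the TI/T1 space.
#'
#' @slot v1 4-D numeric array `(nx, ny, nz, 3)` of per-voxel direction
#'   vectors; zero vectors mark voxels without a defined orientation.
#' @slot fa 3-D numeric array of fractional anisotropy values in \[0, 1\].
#' @seealso [fiberField()], [sampleFiberField()], [computeThetaMap()]
#' @exportClass FiberField
setClass("FiberField", representation(v1 = "array", fa = "array"))

setValidity("FiberField", function(object) {
  msg <- character()
  dv <- dim(object@v1)
  df <- dim(object@fa)
  if (length(dv) != 4L || dv[4] != 3L) {
    msg <- c(msg, "v1 must be a 4-D array with 3 components on the 4th axis")
  } else if (length(df) != 3L || !all(dv[1:3] == df)) {
    msg <- c(msg, "fa grid must match the first three dimensions of v1")
  } else {
    if (any(object@fa < 0 | object@fa > 1, na.rm = TRUE)) {
      msg <- c(msg, "fa values must lie in [0, 1]")
    }
    nrm <- sqrt(apply(object@v1^2, c(1, 2, 3), sum))
    bad <- object@fa > 0 & abs(nrm - 1) >= 1e-6
    if (any(bad, na.rm = TRUE)) {
      msg <- c(msg, "v1 must be unit length (within 1e-6) wherever fa > 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Magnitude TI image series
#'
#' A stack of co-registered 3-D magnitude volumes, one per inversion time,
#' together with the acquisition protocol that produced them.
#'
#' @slot data 4-D numeric array `(nx, ny, nz, nTI)`; the 4th axis follows
#'   `tiTimes(protocol)`.
#' @slot protocol an [AcquisitionProtocol-class] object.
#' @slot pixdim numeric length-3 voxel size, mm.
#' @seealso [tiSeries()], [simulateTISeries()], [fitT1Map()]
#' @exportClass TISeries
setClass("TISeries",
  representation(data = "array", protocol = "AcquisitionProtocol",
                 pixdim = "numeric")
)

setValidity("TISeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4-D array (x, y, z, TI)")
  else if (d[4] != length(object@protocol@tiList)) {
    msg <- c(msg, "4th dimension of data must match length(tiList)")
  }
  if (length(object@pixdim) != 3L || any(object@pixdim <= 0)) {
    msg <- c(msg, "pixdim must be 3 positive voxel sizes")
  }
  if (length(msg)) msg else TRUE
})

#' Fiber-to-field angle map
#'
#' Per-voxel angle between the fiber direction and B0, folded into
#' \[0, 90\] degrees (the principal eigenvector is sign-ambiguous, so only
#' the acute angle is defined).
#'
#' @slot theta 3-D numeric array, degrees in \[0, 90\] on valid voxels.
#' @slot validMask 3-D logical array; FALSE where the direction vector was
#'   degenerate (e.g. zero outside the brain).
#' @seealso [computeThetaMap()]
#' @exportClass ThetaMap
setClass("ThetaMap", representation(theta = "array", validMask = "array"))

setValidity("ThetaMap", function(object) {
  msg <- character()
  if (!identical(dim(object@theta), dim(object@validMask))) {
    msg <- c(msg, "theta and validMask must have identical dimensions")
  }
  th <- object@theta[object@validMask]
  if (length(th) && (any(th < 0, na.rm = TRUE) || any(th > 90, na.rm = TRUE))) {
    msg <- c(msg, "theta must lie in [0, 90] degrees on valid voxels")
  }
  if (length(msg)) msg else TRUE
})

#' Result of voxel-wise T1 map fitting
#'
#' @slot t1Map 3-D array, fitted T1 in ms (NA where unsuccessful).
#' @slot r1Map 3-D array, R1 = 1000 / T1 in 1/s.
#' @slot sseMap 3-D array, residual sum of squares of the retained fit.
#' @slot polarityBoundaryMap 3-D integer array, number of leading samples
#'   re-negated by the polarity restoration (0 = none); NA in `"long"` mode.
#' @slot successMask 3-D logical array; TRUE where the fit converged inside
#'   the validity bounds and the voxel was inside the mask.
#' @slot fitMode `"all"` (polarity-restored, all TIs) or `"long"`
#'   (four longest TIs, magnitudes assumed positive).
#' @slot t1Bounds numeric length-2, validity bounds in ms.
#' @seealso [fitT1Map()]
#' @exportClass T1MapResult
setClass("T1MapResult",
  representation(
    t1Map = "array",
    r1Map = "array",
    sseMap = "array",
    polarityBoundaryMap = "array",
    successMask = "array",
    fitMode = "character",
    t1Bounds = "numeric"
  )
)

setValidity("T1MapResult", function(object) {
  msg <- character()
  d <- dim(object@t1Map)
  for (s in c("r1Map", "sseMap", "polarityBoundaryMap", "successMask")) {
    if (!identical(dim(slot(object, s)), d)) {
      msg <- c(msg, sprintf("%s must match the t1Map dimensions", s))
    }
  }
  if (!object@fitMode %in% c("all", "long")) {
    msg <- c(msg, "fitMode must be 'all' or 'long'")
  }
  ok <- object@successMask
  if (any(ok)) {
    t1 <- object@t1Map[ok]
    r1 <- object@r1Map[ok]
    if (any(t1 < object@t1Bounds[1] | t1 > object@t1Bounds[2])) {
      msg <- c(msg, "successful voxels must satisfy the T1 validity bounds")
    }
    if (any(abs(r1 * t1 - 1000) > 1e-9 * 1000)) {
      msg <- c(msg, "r1Map must equal 1000 / t1Map on successful voxels")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Angular profile of a voxel-wise quantity
#'
#' Binned mean / SD / count of a scalar quantity (T1, R1 or a single-TI
#' signal) against the fiber-to-field angle. Bins tile \[0, 90\] degrees
#' without overlap; the default 9-degree bins have centers 4.5, 13.5, ...,
#' 85.5 degrees. The last bin is closed at 90 degrees so no voxel is lost.
#'
#' @slot binWidth degrees.
#' @slot binCenters degrees.
#' @slot mean per-bin mean of the quantity (NA for empty bins).
#' @slot sd per-bin standard deviation across voxels (NA where n < 2).
#' @slot n per-bin voxel count.
#' @slot quantityLabel e.g. `"t1"`, `"r1"` or `"ti_signal:340"`.
#' @seealso [angularProfile1D()], [tiSignalProfiles()], [quantifyFeatures()]
#' @exportClass AngularProfile
setClass("AngularProfile",
  representation(
    binWidth = "numeric",
    binCenters = "numeric",
    mean = "numeric",
    sd = "numeric",
    n = "integer",
    quantityLabel = "character"
  )
)

setValidity("AngularProfile", function(object) {
  msg <- character()
  k <- length(object@binCenters)
  if (length(object@mean) != k || length(object@sd) != k ||
      length(object@n) != k) {
    msg <- c(msg, "mean, sd and n must have one entry per bin")
  }
  if (abs(k * object@binWidth - 90) > 1e-9) {
    msg <- c(msg, "bins must tile [0, 90] degrees exactly")
  }
  if (any(object@n < 0)) msg <- c(msg, "bin counts must be >= 0")
  if (any(!is.na(object@sd) & object@n < 2L)) {
    msg <- c(msg, "sd must be NA where n < 2")
  }
  if (length(msg)) msg else TRUE
})

#' Two-dimensional angle-by-FA grid of a quantity
#'
#' Cell means of a quantity over joint membership in a fiber-to-field angle
#' bin and an FA bin (FA intervals are left-open, right-closed). Empty cells
#' carry NA means and are excluded from display statistics.
#'
#' @slot binCenters theta bin centers, degrees.
#' @slot binWidth theta bin width, degrees.
#' @slot faEdges ascending FA bin edges in \[0, 1\].
#' @slot mean matrix `(nFA, nTheta)` of cell means.
#' @slot n integer matrix of cell counts.
#' @slot quantityLabel character.
#' @seealso [angularProfile2D()]
#' @exportClass Angular2DGrid
setClass("Angular2DGrid",
  representation(
    binCenters = "numeric",
    binWidth = "numeric",
    faEdges = "numeric",
    mean = "matrix",
    n = "matrix",
    quantityLabel = "character"
  )
)

setValidity("Angular2DGrid", function(object) {
  msg <- character()
  if (any(diff(object@faEdges) <= 0)) msg <- c(msg, "faEdges must be ascending")
  if (!identical(dim(object@mean), dim(object@n))) {
    msg <- c(msg, "mean and n matrices must have identical dimensions")
  }
  if (nrow(object@mean) != length(object@faEdges) - 1L ||
      ncol(object@mean) != length(object@binCenters)) {
    msg <- c(msg, "grid must be (nFA x nTheta)")
  }
  if (length(msg)) msg else TRUE
})

#' Quantified angular features of a T1 or R1 profile
#'
#' The two angular features of white-matter longitudinal relaxation:
#' the 0-to-90-degree difference (from profile endpoints, optionally by
#' linear extrapolation of the first/last two bins) and the broad hump
#' near 40 degrees (baseline-subtracted amplitude, peak angle and
#' interpolated FWHM). Percent features are relative to the mask-wide mean
#' of the quantity.
#'
#' @slot quantityLabel `"t1"` or `"r1"`.
#' @slot delta090 endpoint difference in profile units; for T1 positive when
#'   the 90-degree value exceeds the 0-degree value, for R1 the reverse.
#' @slot humpAmplitude maximal baseline-subtracted residual in the search
#'   window (T1: profile above baseline; R1: below).
#' @slot peakAngle degrees, bin center of the maximal residual.
#' @slot fwhm degrees (NA when undefined).
#' @slot fwhmBounded FALSE when a half-maximum crossing was not bracketed
#'   inside \[0, 90\] degrees.
#' @slot meanValue mask-wide mean of the quantity.
#' @slot pctDelta `100 * |delta090| / meanValue`.
#' @slot pctHump `100 * humpAmplitude / meanValue`.
#' @slot baselineSlope,baselineIntercept the two-anchor baseline line.
#' @slot anchorLow,anchorHigh numeric length-2 `(degrees, units)` anchors.
#' @slot endpoint0,endpoint90 profile values at 0 and 90 degrees.
#' @seealso [quantifyFeatures()], [aggregateFeatures()]
#' @exportClass AngularFeatureSet
setClass("AngularFeatureSet",
  representation(
    quantityLabel = "character",
    delta090 = "numeric",
    humpAmplitude = "numeric",
    peakAngle = "numeric",
    fwhm = "numeric",
    fwhmBounded = "logical",
    meanValue = "numeric",
    pctDelta = "numeric",
    pctHump = "numeric",
    baselineSlope = "numeric",
    baselineIntercept = "numeric",
    anchorLow = "numeric",
    anchorHigh = "numeric",
    endpoint0 = "numeric",
    endpoint90 = "numeric"
  )
)

setValidity("AngularFeatureSet", function(object) {
  msg <- character()
  if (object@humpAmplitude > 0 && !is.na(object@fwhm) && object@fwhm <= 0) {
    msg <- c(msg, "fwhm must be > 0 when a hump is present")
  }
  if (length(msg)) msg else TRUE
})
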