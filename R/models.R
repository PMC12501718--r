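#' Construct an acquisition protocol
#'
#' @param fieldLabel character label, e.g. `"1.5T"`.
#' @param tiList strictly increasing inversion times in ms (>= 4 values).
#' @param tr repetition time in ms.
#' @param readFlip readout flip angle, degrees.
#' @param b0Direction unit 3-vector, direction of B0 in grid coordinates.
#'   Defaults to the third grid axis (scanner z), matching acquisitions
#'   without angulation at scanner coordinates.
#' @return an [AcquisitionProtocol-class] object.
#' @export
acquisitionProtocol <- function(fieldLabel, tiList, tr = 5000, readFlip = 4,
                                b0Direction = c(0, 0, 1)) {
  new("AcquisitionProtocol", fieldLabel = as.character(fieldLabel),
      tiList = as.numeric(tiList), tr = as.numeric(tr),
      readFlip = as.numeric(readFlip), b0Direction = as.numeric(b0Direction))
}

#' Field-strength protocol presets
#'
#' Six-TI inversion-recovery presets for the three common field strengths.
#' The shortest TI follows the field (170 ms at 1.5 T, 200 ms at 3 T and
#' 300 ms at 7 T); the remaining TIs span up to 3000 ms, approximately
#' log-spaced. The exact schedules of any given scanner differ; override
#' `tiList` for real data.
#'
#' @param field `"1.5T"`, `"3T"` or `"7T"`.
#' @param tiList optional override of the inversion times, ms.
#' @param readFlip readout flip angle, degrees (default 4).
#' @param b0Direction unit 3-vector.
#' @return an [AcquisitionProtocol-class].
#' @examples
#' protocolPreset("1.5T")
#' @export
protocolPreset <- function(field = c("1.5T", "3T", "7T"), tiList = NULL,
                           readFlip = 4, b0Direction = c(0, 0, 1)) {
  field <- match.arg(field)
  if (is.null(tiList)) {
    tiList <- switch(field,
      "1.5T" = c(170, 340, 650, 1200, 2000, 3000),
      "3T" = c(200, 390, 740, 1300, 2100, 3000),
      "7T" = c(300, 600, 1000, 1700, 2400, 3000)
    )
  }
  acquisitionProtocol(field, tiList, tr = 5000, readFlip = readFlip,
                      b0Direction = b0Direction)
}

#' Short-compartment T1 by field strength
#'
#' The fast-relaxing (myelin-associated) T1 component is strongly field
#' dependent; the values used for the two-pool phantom presets are 120 ms at
#' 1.5 T, 260 ms at 3 T and 540 ms at 7 T.
#'
#' @param field `"1.5T"`, `"3T"` or `"7T"`.
#' @return T1 of the short compartment in ms.
#' @export
shortT1ForField <- function(field = c("1.5T", "3T", "7T")) {
  field <- match.arg(field)
  switch(field, "1.5T" = 120, "3T" = 260, "7T" = 540)
}

#' Construct a ground-truth angular T1 model
#'
#' @param t1Parallel T1 at 0 degrees, ms.
#' @param delta090 linear 0-to-90-degree increase, ms.
#' @param humpAmplitude Gaussian hump amplitude, ms.
#' @param humpCenter hump center, degrees.
#' @param humpFwhm hump FWHM, degrees.
#' @return an [AngularT1Model-class].
#' @seealso [calibrateParallelT1()] to fix the mask-wide mean T1.
#' @export
angularT1Model <- function(t1Parallel, delta090 = 27, humpAmplitude = 23.5,
                           humpCenter = 40, humpFwhm = 34) {
  new("AngularT1Model", t1Parallel = as.numeric(t1Parallel),
      delta090 = as.numeric(delta090),
      humpAmplitude = as.numeric(humpAmplitude),
      humpCenter = as.numeric(humpCenter), humpFwhm = as.numeric(humpFwhm))
}

#' Construct a two-pool recovery model
#'
#' Defaults emulate the 1.5 T phenomenology: a 120 ms short compartment
#' whose signal fraction is depressed near 40 degrees
#' (`fractionShortHumpAmplitude < 0`), so that the apparent
#' mono-exponential T1 fitted from all TIs shows the broad long-T1 hump
#' there while a fit restricted to the four longest TIs does not.
#'
#' @param t1Short short-compartment T1, ms.
#' @param t1Long long-compartment T1, ms.
#' @param fractionShortBaseline short-pool fraction away from the hump.
#' @param fractionShortHumpAmplitude signed fraction change at the center.
#' @param humpCenter,humpFwhm hump geometry, degrees.
#' @return a [TwoPoolModel-class].
#' @export
twoPoolModel <- function(t1Short = 120, t1Long = 564,
                         fractionShortBaseline = 0.2,
                         fractionShortHumpAmplitude = -0.12,
                         humpCenter = 40, humpFwhm = 34) {
  new("TwoPoolModel", t1Short = as.numeric(t1Short),
      t1Long = as.numeric(t1Long),
      fractionShortBaseline = as.numeric(fractionShortBaseline),
      fractionShortHumpAmplitude = as.numeric(fractionShortHumpAmplitude),
      humpCenter = as.numeric(humpCenter), humpFwhm = as.numeric(humpFwhm))
}

#' Construct a noise specification
#'
#' @param model `"none"` or `"rician"`.
#' @param sigma per-channel Gaussian SD in signal units. The default
#'   amplitude used by [simulateTISeries()] is 1000, so `sigma = 20`
#'   corresponds to a signal-to-noise ratio of 50.
#' @param seed optional integer RNG seed; NA leaves the RNG state alone.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(model = c("rician", "none"), sigma = 20, seed = NA) {
  model <- match.arg(model)
  new("NoiseSpec", model = model, sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' @rdname predictT1
setMethod("predictT1", "AngularT1Model", function(model, theta) {
  stopifnot(is.numeric(theta))
  model@t1Parallel + model@delta090 * theta / 90 +
    model@humpAmplitude * gaussHump(theta, model@humpCenter, model@humpFwhm)
})

#' @rdname predictT1
setMethod("predictT1", "TwoPoolModel", function(model, theta) {
  rep(model@t1Long, length(theta))
})

#' @rdname predictT1
setMethod("shortFraction", "TwoPoolModel", function(model, theta) {
  model@fractionShortBaseline + model@fractionShortHumpAmplitude *
    gaussHump(theta, model@humpCenter, model@humpFwhm)
})

#' @rdname predictT1
setMethod("shortFraction", "AngularT1Model", function(model, theta) {
  rep(0, length(theta))
})

#' Calibrate the parallel T1 to a target mask-wide mean
#'
#' For fiber directions uniform on the sphere the fiber-to-field angle has
#' density sin(theta) on \[0, 90\] degrees, so the expected mask-wide mean
#' T1 of a phantom is the sin-weighted integral of the angular model.
#' This sets `t1Parallel` such that that expectation equals `targetMean`.
#'
#' @param model an [AngularT1Model-class].
#' @param targetMean desired expected mask-wide mean T1, ms.
#' @return the model with `t1Parallel` replaced.
#' @examples
#' m <- calibrateParallelT1(angularT1Model(500), targetMean = 564.1)
#' @export
calibrateParallelT1 <- function(model, targetMean) {
  stopifnot(is(model, "AngularT1Model"), is.numeric(targetMean))
  rad <- pi / 180
  f <- function(th) predictT1(model, th) * sin(th * rad) * rad
  m0 <- stats::integrate(f, 0, 90, rel.tol = 1e-10)$value  # sin integrates to 1
  model@t1Parallel <- model@t1Parallel + (targetMean - m0)
  validObject(model)
  model
}
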