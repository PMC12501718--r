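#' Profile endpoint values at 0 and 90 degrees
#'
#' The 0-degree value is either the first-bin mean or, with
#' `extrapolate0 = TRUE` (the default, matching the convention of
#' estimating the 0-degree point by linear extrapolation of the 4.5- and
#' 13.5-degree bins), the straight line through the first two bin centers
#' evaluated at 0. Symmetrically for 90 degrees through the last two
#' centers (`extrapolate90`, default FALSE: the last-bin mean is used).
#'
#' @param profile an [AngularProfile-class] with populated first two and
#'   last two bins.
#' @param extrapolate0,extrapolate90 logical flags.
#' @return named numeric `c(value0, value90)`.
#' @examples
#' p <- syntheticProfile(560 + 2/9 * ((1:10) * 9 - 4.5))  # linear profile
#' profileEndpoints(p)  # 559 at 0 degrees
#' @export
profileEndpoints <- function(profile, extrapolate0 = TRUE,
                             extrapolate90 = FALSE) {
  stopifnot(is(profile, "AngularProfile"))
  k <- length(profile@binCenters)
  needed <- c(1L, 2L, k - 1L, k)
  empty <- needed[profile@n[needed] == 0L]
  if (length(empty)) {
    stop(sprintf("unpopulated anchor bin(s) at %s degrees",
                 paste(profile@binCenters[empty], collapse = ", ")))
  }
  cc <- profile@binCenters
  mu <- profile@mean
  v0 <- if (extrapolate0) {
    mu[1] + (mu[2] - mu[1]) / (cc[2] - cc[1]) * (0 - cc[1])
  } else {
    mu[1]
  }
  v90 <- if (extrapolate90) {
    mu[k] + (mu[k] - mu[k - 1]) / (cc[k] - cc[k - 1]) * (90 - cc[k])
  } else {
    mu[k]
  }
  c(value0 = v0, value90 = v90)
}

#' Two-anchor baseline of an angular profile
#'
#' The baseline is the straight line joining the means of the profile
#' values over 0-20 degrees and over 80-90 degrees. Each anchor sits at the
#' mean of the populated bin centers inside its window, with the unweighted
#' mean of those bins' means as ordinate.
#'
#' @param profile an [AngularProfile-class].
#' @param lowWindow,highWindow degree intervals for the two anchors.
#' @return list with `slope`, `intercept` (units per degree / units) and
#'   the two anchors as `(degrees, value)` pairs.
#' @export
profileBaseline <- function(profile, lowWindow = c(0, 20),
                            highWindow = c(80, 90)) {
  stopifnot(is(profile, "AngularProfile"))
  anchor <- function(win) {
    in_win <- profile@binCenters >= win[1] & profile@binCenters <= win[2] &
      profile@n > 0L
    if (!any(in_win)) {
      stop(sprintf("no populated bins in the %g-%g degree anchor window",
                   win[1], win[2]))
    }
    c(mean(profile@binCenters[in_win]), mean(profile@mean[in_win]))
  }
  lo <- anchor(lowWindow)
  hi <- anchor(highWindow)
  slope <- (hi[2] - lo[2]) / (hi[1] - lo[1])
  list(slope = slope, intercept = lo[2] - slope * lo[1],
       anchorLow = lo, anchorHigh = hi)
}

#' Quantify the broad angular hump of a profile
#'
#' Subtracts the baseline from the profile (T1: profile minus baseline,
#' `sense = "peak"`; R1: baseline minus profile, `sense = "dip"`), takes the
#' maximal residual over the bins whose centers lie in the search window as
#' the amplitude, and measures the full width at half maximum by linear
#' interpolation of the residual between adjacent bin centers on each side
#' of the peak. A half-maximum crossing not bracketed inside \[0, 90\]
#' degrees flags the FWHM as unbounded.
#'
#' @param profile an [AngularProfile-class].
#' @param baseline a baseline as returned by [profileBaseline()]; computed
#'   from the profile when NULL.
#' @param window degree interval searched for the peak (default 20-70,
#'   generous around the reported 40-degree center).
#' @param sense `"peak"` or `"dip"`.
#' @return list with `amplitude`, `peakAngle`, `fwhm`, `fwhmBounded`,
#'   `residuals` (per-bin) and the baseline used. All residuals <= 0 in the
#'   window give amplitude 0 and an undefined (NA) FWHM.
#' @export
profileHump <- function(profile, baseline = NULL, window = c(20, 70),
                        sense = c("peak", "dip")) {
  stopifnot(is(profile, "AngularProfile"))
  sense <- match.arg(sense)
  if (is.null(baseline)) baseline <- profileBaseline(profile)
  cc <- profile@binCenters
  base <- baseline$intercept + baseline$slope * cc
  res <- if (sense == "peak") profile@mean - base else base - profile@mean
  inWin <- cc >= window[1] & cc <= window[2] & profile@n > 0L
  if (sum(inWin) < 3L) stop("need >= 3 populated bins in the search window")
  if (all(res[inWin] <= 0, na.rm = TRUE)) {
    return(list(amplitude = 0, peakAngle = NA_real_, fwhm = NA_real_,
                fwhmBounded = FALSE, residuals = res, baseline = baseline))
  }
  iPeak <- which(inWin)[which.max(res[inWin])]
  amp <- res[iPeak]
  half <- amp / 2

  interpCross <- function(idx, dir) {
    # walk from the peak in direction dir until the residual drops below
    # half; linear interpolation between the bracketing bin centers
    i <- idx
    repeat {
      j <- i + dir
      if (j < 1L || j > length(cc) || is.na(res[j])) return(NA_real_)
      if (res[j] <= half) {
        return(cc[i] + (cc[j] - cc[i]) * (res[i] - half) / (res[i] - res[j]))
      }
      i <- j
    }
  }
  left <- interpCross(iPeak, -1L)
  right <- interpCross(iPeak, +1L)
  bounded <- !is.na(left) && !is.na(right)
  list(amplitude = amp, peakAngle = cc[iPeak],
       fwhm = if (bounded) right - left else NA_real_,
       fwhmBounded = bounded, residuals = res, baseline = baseline)
}

#' Quantify the two angular features of a T1 or R1 profile
#'
#' Combines [profileEndpoints()], [profileBaseline()] and [profileHump()]
#' into an [AngularFeatureSet-class]: the 0-to-90-degree difference (for T1
#' positive when the 90-degree value is larger; for R1 the reverse, since
#' R1 decreases with angle), the baseline-subtracted hump amplitude (T1:
#' peak; R1: dip), its peak angle and FWHM, and the percent features
#' relative to the mask-wide mean.
#'
#' @param profile an [AngularProfile-class] with label `"t1"` or `"r1"`.
#' @param meanValue mask-wide mean of the quantity (e.g. mean of
#'   `t1Map(fit)` over the analysis mask), used for the percent features.
#' @param sense `"peak"` (T1) or `"dip"` (R1); inferred from the label by
#'   default.
#' @param extrapolate0,extrapolate90 endpoint conventions, see
#'   [profileEndpoints()].
#' @param window hump search window, degrees.
#' @return an [AngularFeatureSet-class].
#' @examples
#' p <- syntheticProfile(560 + 27 * ((1:10) * 9 - 4.5) / 90 +
#'   23.5 * exp(-4 * log(2) * ((1:10) * 9 - 4.5 - 40)^2 / 34^2))
#' quantifyFeatures(p, meanValue = 564.1)
#' @export
quantifyFeatures <- function(profile, meanValue, sense = NULL,
                             extrapolate0 = TRUE, extrapolate90 = FALSE,
                             window = c(20, 70)) {
  stopifnot(is(profile, "AngularProfile"))
  lbl <- profile@quantityLabel
  if (is.null(sense)) {
    sense <- if (identical(lbl, "r1")) "dip" else "peak"
  }
  ep <- profileEndpoints(profile, extrapolate0, extrapolate90)
  delta <- if (sense == "peak") ep[["value90"]] - ep[["value0"]]
           else ep[["value0"]] - ep[["value90"]]
  base <- profileBaseline(profile)
  h <- profileHump(profile, base, window = window, sense = sense)
  new("AngularFeatureSet",
      quantityLabel = lbl,
      delta090 = delta,
      humpAmplitude = h$amplitude,
      peakAngle = if (is.na(h$peakAngle)) NA_real_ else h$peakAngle,
      fwhm = h$fwhm,
      fwhmBounded = h$fwhmBounded,
      meanValue = meanValue,
      pctDelta = 100 * abs(delta) / meanValue,
      pctHump = 100 * h$amplitude / meanValue,
      baselineSlope = base$slope,
      baselineIntercept = base$intercept,
      anchorLow = base$anchorLow,
      anchorHigh = base$anchorHigh,
      endpoint0 = ep[["value0"]],
      endpoint90 = ep[["value90"]])
}

#' Aggregate feature sets across datasets
#'
#' Per-field mean, SD and n over a list of [AngularFeatureSet-class]
#' objects (one per subject/dataset); optionally Welch and paired t
#' statistics between two groups.
#'
#' @param featureSets list of [AngularFeatureSet-class] with a common
#'   quantity label.
#' @param group2 optional second list for a two-group comparison.
#' @param paired also compute the paired t-test (requires equal lengths).
#' @return list with `summary` (data.frame of mean/sd/n per field) and,
#'   when `group2` is given, `welch` and (if `paired`) `paired` htest
#'   results per field.
#' @export
aggregateFeatures <- function(featureSets, group2 = NULL, paired = FALSE) {
  toDF <- function(sets) {
    if (!length(sets)) stop("need at least one feature set")
    lbl <- unique(vapply(sets, function(s) s@quantityLabel, character(1)))
    if (length(lbl) != 1L) stop("mixed quantity labels")
    do.call(rbind, lapply(sets, as.data.frame))
  }
  df <- toDF(featureSets)
  fields <- c("delta_0_90", "pct_delta", "hump_amplitude", "pct_hump",
              "peak_angle", "fwhm", "mean_value")
  summ <- data.frame(
    field = fields,
    mean = vapply(fields, function(f) mean(df[[f]], na.rm = TRUE), 0),
    sd = vapply(fields, function(f) {
      x <- df[[f]][!is.na(df[[f]])]
      if (length(x) >= 2L) stats::sd(x) else NA_real_
    }, 0),
    n = vapply(fields, function(f) sum(!is.na(df[[f]])), 0L),
    row.names = NULL
  )
  out <- list(summary = summ, quantity = df$quantity[1])
  safeT <- function(x, y, ...) {
    # degenerate fields (all NA, or zero variance) yield NULL, not an error
    tryCatch(stats::t.test(x, y, ...), error = function(e) NULL)
  }
  if (!is.null(group2)) {
    df2 <- toDF(group2)
    out$welch <- lapply(stats::setNames(fields, fields), function(f) {
      safeT(df[[f]], df2[[f]])
    })
    if (paired) {
      if (nrow(df) != nrow(df2)) stop("paired test requires equal group sizes")
      out$paired <- lapply(stats::setNames(fields, fields), function(f) {
        safeT(df[[f]], df2[[f]], paired = TRUE)
      })
    }
  }
  out
}

#' Build an angular profile from explicit bin means
#'
#' Convenience constructor used in examples and for feeding externally
#' tabulated profiles (e.g. published group means) into the feature
#' quantification. Bin counts default to a large value so every bin counts
#' as populated; SDs default to NA.
#'
#' @param means per-bin mean values, ordered from the first bin.
#' @param binWidth degrees (length of `means` times `binWidth` must be 90).
#' @param n per-bin counts.
#' @param sd per-bin SDs.
#' @param quantityLabel label.
#' @return an [AngularProfile-class].
#' @export
syntheticProfile <- function(means, binWidth = 90 / length(means),
                             n = rep(1000L, length(means)),
                             sd = rep(NA_real_, length(means)),
                             quantityLabel = "t1") {
  nb <- length(means)
  new("AngularProfile", binWidth = binWidth,
      binCenters = (seq_len(nb) - 0.5) * binWidth,
      mean = as.numeric(means), sd = as.numeric(sd), n = as.integer(n),
      quantityLabel = quantityLabel)
}

#' Round half away from zero
#'
#' Report-style rounding: 4.45 rounds to 4.5 at one decimal (base R's
#' `round` rounds half to even). Used to format feature percentages.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @examples
#' roundHalfUp(4.857, 1)  # 4.9
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
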