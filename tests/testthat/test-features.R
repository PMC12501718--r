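linearProfile <- function(slope, intercept, binWidth = 9) {
  cc <- (seq_len(90 / binWidth) - 0.5) * binWidth
  syntheticProfile(intercept + slope * cc, binWidth = binWidth)
}

test_that("endpoints are exact on linear profiles and handle flats", {
  p <- linearProfile(2 / 9, 560)
  ep <- profileEndpoints(p, extrapolate0 = TRUE, extrapolate90 = TRUE)
  expect_equal(unname(ep), c(560, 560 + 2 / 9 * 90))
  flat <- linearProfile(0, 700)
  epf <- profileEndpoints(flat)
  expect_equal(epf[["value0"]], epf[["value90"]])
  # hand-computed: means 560 at 4.5 deg and 562 at 13.5 deg -> 559 at 0
  p2 <- syntheticProfile(c(560, 562, rep(570, 8)))
  expect_equal(profileEndpoints(p2)[["value0"]], 559)
  # without extrapolation the first/last bin means are returned
  ep3 <- profileEndpoints(p2, extrapolate0 = FALSE, extrapolate90 = FALSE)
  expect_equal(unname(ep3), c(560, 570))
  # unpopulated anchor bins are named in the error
  bad <- syntheticProfile(rep(600, 10), n = c(0L, rep(1000L, 9)))
  expect_error(profileEndpoints(bad), "4.5")
})

test_that("the two-anchor baseline reproduces hand computations", {
  flat <- linearProfile(0, 590)
  b <- profileBaseline(flat)
  expect_equal(b$slope, 0)
  expect_equal(b$intercept, 590)
  lin <- linearProfile(0.3, 500)
  bl <- profileBaseline(lin)
  expect_equal(bl$slope, 0.3)
  expect_equal(bl$intercept, 500)
  # only bins 4.5 (560), 13.5 (562) and 85.5 (590) populated:
  # line through (9, 561) and (85.5, 590)
  p <- syntheticProfile(c(560, 562, rep(0, 7), 590),
                        n = c(10L, 10L, rep(0L, 7), 10L))
  b2 <- profileBaseline(p)
  expect_equal(b2$anchorLow, c(9, 561))
  expect_equal(b2$anchorHigh, c(85.5, 590))
  expect_equal(b2$slope, (590 - 561) / (85.5 - 9))
  empty <- syntheticProfile(rep(1, 10), n = c(0L, 0L, rep(10L, 8)))
  expect_error(profileBaseline(empty), "anchor window")
})

test_that("Gaussian residuals are quantified against a dense-grid oracle", {
  A <- 23.5
  F <- 34.2
  cc <- (1:10) * 9 - 4.5
  p <- syntheticProfile(A * gaussianHump(cc, 40, F))
  zero <- list(slope = 0, intercept = 0,
               anchorLow = c(0, 0), anchorHigh = c(90, 0))
  h <- profileHump(p, zero)
  # oracle: the same Gaussian on a dense grid
  dense <- seq(0, 90, by = 0.001)
  g <- A * gaussianHump(dense, 40, F)
  trueAmp <- max(g)
  cross <- range(dense[g >= trueAmp / 2])
  expect_rel_equal(h$amplitude, trueAmp, 0.02)
  expect_lt(abs(h$fwhm - (cross[2] - cross[1])), 2)
  expect_equal(h$peakAngle, 40.5)
})

test_that("flat residuals yield zero amplitude and undefined FWHM", {
  p <- linearProfile(0.2, 500)
  h <- profileHump(p)  # baseline coincides with the profile
  expect_equal(h$amplitude, 0)
  expect_true(is.na(h$fwhm))
})

test_that("triangular residuals give the half-base FWHM", {
  # peak 10 at 45 deg, zero at 27 and 63; 10-degree bins sample the apex
  cc <- (1:9) * 10 - 5
  res <- pmax(0, 10 * (1 - abs(cc - 45) / 18))
  p <- syntheticProfile(res, binWidth = 10)
  zero <- list(slope = 0, intercept = 0,
               anchorLow = c(0, 0), anchorHigh = c(90, 0))
  h <- profileHump(p, zero, window = c(20, 70))
  expect_equal(h$amplitude, 10)
  expect_equal(h$fwhm, 18)
})

test_that("an off-scale hump is flagged as unbounded", {
  cc <- (1:10) * 9 - 4.5
  p <- syntheticProfile(10 * gaussianHump(cc, 65, 80))
  zero <- list(slope = 0, intercept = 0,
               anchorLow = c(0, 0), anchorHigh = c(90, 0))
  h <- profileHump(p, zero, window = c(20, 70))
  expect_false(h$fwhmBounded)
  expect_true(is.na(h$fwhm))
})

test_that("quantified percentages reproduce one-decimal arithmetic", {
  # linear T1 profile with an exact 27.4 ms span, plus endpoint extrapolation
  p <- linearProfile(27.4 / 90, 550)
  fs <- quantifyFeatures(p, meanValue = 564.1, extrapolate90 = TRUE)
  expect_equal(fs@delta090, 27.4)
  expect_equal(roundHalfUp(fs@pctDelta, 1), 4.9)
  # R1 sense: positive when the 0-degree value exceeds the 90-degree one
  pr <- linearProfile(-0.0819 / 90, 1.81)
  pr@quantityLabel <- "r1"
  fr <- quantifyFeatures(pr, meanValue = 1.774, extrapolate90 = TRUE)
  expect_equal(fr@delta090, 0.0819)
  expect_gt(fr@delta090, 0)
})

test_that("injected line-plus-hump profiles are recovered within binning error", {
  # hump centered on a bin center and narrow enough to vanish at the
  # baseline anchors, so the conventions introduce no attenuation
  cc <- (1:10) * 9 - 4.5
  delta <- 27
  A <- 23.5
  p <- syntheticProfile(537 + delta * cc / 90 + A * gaussianHump(cc, 40.5, 18))
  fs <- quantifyFeatures(p, meanValue = 564, extrapolate90 = TRUE)
  expect_lt(abs(fs@delta090 - delta), 0.1)
  expect_rel_equal(fs@humpAmplitude, A, 0.02)
  expect_lt(abs(fs@fwhm - 18), 2)
  expect_equal(fs@peakAngle, 40.5)
})

test_that("R1 dip and T1 hump amplitudes are reciprocally coherent", {
  cc <- (1:10) * 9 - 4.5
  t1 <- 560 + 10 * gaussianHump(cc, 40.5, 25)  # hump < 5% of the mean
  pT1 <- syntheticProfile(t1)
  pR1 <- syntheticProfile(1000 / t1, quantityLabel = "r1")
  fT1 <- quantifyFeatures(pT1, 562)
  fR1 <- quantifyFeatures(pR1, 1000 / 562)
  # first-order propagation of r1 = 1000 / t1: dR1 = 1000 * dT1 / T1^2
  predicted <- fT1@humpAmplitude / 562^2 * 1000
  expect_rel_equal(fR1@humpAmplitude, predicted, 0.15)
})

test_that("feature aggregation matches hand-computed statistics", {
  mk <- function(delta) {
    p <- linearProfile(delta / 90, 550)
    quantifyFeatures(p, meanValue = 564, extrapolate90 = TRUE)
  }
  same <- aggregateFeatures(list(mk(20), mk(20), mk(20)))
  srow <- same$summary[same$summary$field == "delta_0_90", ]
  expect_equal(srow$mean, 20)
  expect_equal(srow$sd, 0)
  two <- aggregateFeatures(list(mk(1), mk(3)))
  trow <- two$summary[two$summary$field == "delta_0_90", ]
  expect_equal(trow$mean, 2)
  expect_equal(trow$sd, sqrt(2))
  # Welch t statistic against the textbook formula
  g1 <- list(mk(10), mk(12), mk(14))
  g2 <- list(mk(20), mk(26), mk(23))
  res <- aggregateFeatures(g1, g2, paired = TRUE)
  x <- c(10, 12, 14); y <- c(20, 26, 23)
  tHand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(unname(res$welch$delta_0_90$statistic), tHand)
  dHand <- x - y
  tPaired <- mean(dHand) / (sd(dHand) / sqrt(3))
  expect_equal(unname(res$paired$delta_0_90$statistic), tPaired)
  # mixed quantity labels refuse to aggregate
  bad <- mk(10); bad@quantityLabel <- "r1"
  expect_error(aggregateFeatures(list(mk(10), bad)), "mixed")
})

test_that("zero-feature profiles quantify to all zeros", {
  p <- linearProfile(0, 600)
  fs <- quantifyFeatures(p, meanValue = 600)
  expect_equal(fs@delta090, 0)
  expect_equal(fs@humpAmplitude, 0)
  expect_equal(fs@pctDelta, 0)
  expect_equal(fs@pctHump, 0)
})
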