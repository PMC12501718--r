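test_that("sampled fiber fields respect FA ranges and unit normalisation", {
  ff <- sampleFiberField(c(16, 16, 16), faRangeHigh = c(0.5, 0.8),
                         fracHigh = 1, seed = 11)
  fa <- fiberFA(ff)
  expect_true(all(fa >= 0.5 & fa <= 0.8))
  nrm <- sqrt(apply(fiberV1(ff)^2, c(1, 2, 3), sum))
  expect_true(all(abs(nrm - 1) < 1e-9))
  expect_error(sampleFiberField(c(0, 4, 4)), "dimensions")
})

test_that("fiber sampling is bit-identical under a fixed seed", {
  a <- sampleFiberField(c(12, 12, 12), seed = 42)
  b <- sampleFiberField(c(12, 12, 12), seed = 42)
  expect_identical(fiberV1(a), fiberV1(b))
  expect_identical(fiberFA(a), fiberFA(b))
})

test_that("uniform-sphere sampling yields the sin(theta) angle law", {
  ff <- sampleFiberField(c(32, 32, 32), fracHigh = 1, seed = 7)
  th <- thetaDegrees(computeThetaMap(ff))
  bins <- cut(as.vector(th), breaks = seq(0, 90, by = 9),
              include.lowest = TRUE)
  obs <- as.vector(table(bins))
  edges <- seq(0, 90, by = 9) * pi / 180
  p <- diff(-cos(edges))  # integral of sin over each bin
  gof <- stats::chisq.test(obs, p = p / sum(p))
  expect_gt(gof$p.value, 0.01)
})

test_that("theta bins are all well populated at moderate grid sizes", {
  ff <- sampleFiberField(c(20, 20, 20), fracHigh = 0.5, seed = 3)
  th <- computeThetaMap(ff)
  high <- fiberFA(ff) > 0.5
  bins <- floor(pmin(thetaDegrees(th)[high], 89.999) / 9)
  counts <- tabulate(bins + 1L, 10L)
  expect_true(all(counts >= 20L))
})

test_that("noiseless single-pool series obey null point and asymptote", {
  eta <- 0.96
  t1 <- 600
  tiNull <- t1 * log(1 + eta)
  proto <- acquisitionProtocol("custom", c(150, tiNull, 2500, 10 * t1))
  ff <- constantFiberField(c(3, 3, 3))  # theta = 0
  truth <- angularT1Model(t1Parallel = t1, delta090 = 0, humpAmplitude = 0)
  sim <- simulateTISeries(ff, truth, proto, amplitude = 1000,
                          invEfficiency = eta, noise = noiseSpec("none"))
  s <- seriesData(sim$series)
  expect_lt(max(abs(s[, , , 2])), 1e-9)                 # null point
  expect_lt(max(abs(s[, , , 4] - 1000)),
            (1 + eta) * 1000 * exp(-10) + 1e-9)         # asymptote
  expect_equal(unique(as.vector(sim$truthT1)), t1)
})

test_that("Rician replicate means match the noiseless signal at high SNR", {
  N <- 20^3
  ff <- constantFiberField(c(20, 20, 20))
  truth <- angularT1Model(t1Parallel = 537.7)
  proto <- protocolPreset("1.5T")
  clean <- simulateTISeries(ff, truth, proto, noise = noiseSpec("none"))
  noisy <- simulateTISeries(ff, truth, proto,
                            noise = noiseSpec("rician", sigma = 20,
                                              seed = 9))
  sigma <- 20
  for (k in c(1, 4, 5, 6)) {  # TIs away from the null crossing
    s0 <- clean$series@data[1, 1, 1, k]
    mc <- mean(noisy$series@data[, , , k])
    tol <- 3 * sigma / sqrt(N) + sigma^2 / (2 * s0)  # sampling + Rician floor
    expect_lt(abs(mc - s0), tol)
  }
})

test_that("the full-series fit inverts the noiseless phantom exactly", {
  ff <- sampleFiberField(c(8, 8, 8), fracHigh = 1, seed = 5)
  sim <- simulateTISeries(ff, truth15T(), protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  fit <- fitT1Map(sim$series, mode = "all")
  ok <- successMask(fit)
  expect_true(all(ok))
  relErr <- abs(t1Map(fit)[ok] - sim$truthT1[ok]) / sim$truthT1[ok]
  expect_lt(max(relErr), 1e-6)
})

test_that("two-pool phantoms show the hump in all-TI but not long-TI fits", {
  tp <- twoPoolModel(t1Short = shortT1ForField("1.5T"), t1Long = 564)
  ff <- sampleFiberField(c(24, 24, 24), fracHigh = 1, seed = 31)
  sim <- simulateTISeries(ff, tp, protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  th <- computeThetaMap(ff)
  hump <- function(mode) {
    fit <- fitT1Map(sim$series, mode = mode)
    p <- angularProfile1D(t1Map(fit), th, successMask(fit), 9, "t1")
    profileHump(p)$amplitude
  }
  hAll <- hump("all")
  hLong <- hump("long")
  expect_gt(hAll, 10)            # the 40-degree hump is present
  expect_lt(hLong, 0.5 * hAll)   # and greatly reduced in the long-TI fit
})

test_that("model constructors validate their invariants", {
  expect_error(angularT1Model(-5), "t1Parallel")
  expect_error(angularT1Model(500, humpFwhm = -1), "humpFwhm")
  expect_error(twoPoolModel(t1Short = 600, t1Long = 564), "t1Short")
  expect_error(twoPoolModel(fractionShortBaseline = 0.9,
                            fractionShortHumpAmplitude = 0.2), "fraction")
  m <- calibrateParallelT1(angularT1Model(400), 564.1)
  th <- seq(0, 90, by = 0.5)
  expect_true(all(predictT1(m, th) > 0))
})
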