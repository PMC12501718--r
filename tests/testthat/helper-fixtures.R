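# Shared fixture builders. All fixtures are generated in code; no data
# files ship with the tests.

# Fiber field with every voxel pointing the same way (theta known exactly).
constantFiberField <- function(dims, v = c(0, 0, 1), fa = 0.7) {
  v <- v / sqrt(sum(v^2))
  v1 <- array(0, dim = c(dims, 3))
  for (k in 1:3) v1[, , , k] <- v[k]
  fiberField(v1, array(fa, dim = dims))
}

# Gaussian hump used by the ground-truth model, for oracle computations.
gaussianHump <- function(theta, center, fwhm) {
  exp(-4 * log(2) * (theta - center)^2 / fwhm^2)
}

# Standard 1.5 T truth used by the end-to-end tests: Table-level feature
# scale (delta 27 ms, hump 23.5 ms FWHM 34 deg, mask mean 564.1 ms).
truth15T <- function() {
  calibrateParallelT1(
    angularT1Model(t1Parallel = 500, delta090 = 27, humpAmplitude = 23.5,
                   humpCenter = 40, humpFwhm = 34),
    targetMean = 564.1
  )
}

# Dense synthetic ThetaMap covering [0, 90] uniformly (no fiber field).
uniformThetaMap <- function(n = 9000) {
  th <- seq(0, 90, length.out = n)
  dims <- c(n, 1, 1)
  new("ThetaMap", theta = array(th, dim = dims),
      validMask = array(TRUE, dim = dims))
}

expect_rel_equal <- function(object, expected, rtol) {
  expect_lt(abs(object - expected), rtol * abs(expected))
}
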