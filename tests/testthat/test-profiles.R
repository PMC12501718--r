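test_that("constant volumes give flat profiles with zero SD", {
  th <- uniformThetaMap(2000)
  v <- array(600, dim = dim(thetaDegrees(th)))
  p <- angularProfile1D(v, th, NULL, 9, "t1")
  expect_true(all(p@mean == 600))
  expect_true(all(p@sd == 0))
  expect_identical(sum(binCounts(p)), 2000L)
})

test_that("bin means match a brute-force per-bin average oracle", {
  set.seed(41)
  n <- 5000
  thv <- runif(n, 0, 90)
  dims <- c(n, 1, 1)
  th <- new("ThetaMap", theta = array(thv, dims),
            validMask = array(TRUE, dims))
  vals <- array(thv, dims)  # value = angle
  p <- angularProfile1D(vals, th, NULL, 9, "theta")
  bin <- pmin(floor(thv / 9), 9) + 1
  oracle <- vapply(1:10, function(b) mean(thv[bin == b]), numeric(1))
  expect_equal(p@mean, oracle)
  oracleSD <- vapply(1:10, function(b) sd(thv[bin == b]), numeric(1))
  expect_equal(p@sd, oracleSD)
  # dense uniform theta: bin means approach bin centers
  pd <- angularProfile1D(thetaDegrees(uniformThetaMap(90000)),
                         uniformThetaMap(90000), NULL, 9, "theta")
  expect_lt(max(abs(pd@mean - binCenters(pd))), 0.1)
})

test_that("a voxel at exactly 90 degrees lands in the last bin", {
  dims <- c(3, 1, 1)
  th <- new("ThetaMap", theta = array(c(0, 45, 90), dims),
            validMask = array(TRUE, dims))
  p <- angularProfile1D(array(1, dims), th, NULL, 9, "x")
  expect_identical(binCounts(p)[10], 1L)
  expect_identical(sum(binCounts(p)), 3L)
})

test_that("no voxel is lost or double counted across bins", {
  ff <- sampleFiberField(c(14, 14, 14), seed = 2)
  th <- computeThetaMap(ff)
  m <- faMask(ff, 0.5, 0.8)
  v <- array(rnorm(14^3), dim = c(14, 14, 14))
  p <- angularProfile1D(v, th, m, 9, "x")
  expect_identical(sum(binCounts(p)), sum(m & validMask(th)))
})

test_that("an empty mask warns and returns an all-zero profile", {
  th <- uniformThetaMap(100)
  v <- array(1, dim = dim(thetaDegrees(th)))
  expect_warning(
    p <- angularProfile1D(v, th, array(FALSE, dim = dim(v)), 9, "x"),
    "empty"
  )
  expect_true(all(binCounts(p) == 0L))
})

test_that("binned R1 differs from the reciprocal of binned T1", {
  # heterogeneous bins: mean(1/x) != 1/mean(x)
  dims <- c(4, 1, 1)
  th <- new("ThetaMap", theta = array(c(1, 2, 3, 4), dims),
            validMask = array(TRUE, dims))
  t1 <- array(c(400, 800, 500, 700), dims)
  pT1 <- angularProfile1D(t1, th, NULL, 9, "t1")
  pR1 <- angularProfile1D(1000 / t1, th, NULL, 9, "r1")
  expect_equal(pR1@mean[1], mean(1000 / c(400, 800, 500, 700)))
  expect_gt(abs(pR1@mean[1] - 1000 / pT1@mean[1]), 1e-3)
})

test_that("2-D grids marginalise to the 1-D profile over one FA cell", {
  ff <- sampleFiberField(c(12, 12, 12), seed = 6)
  sim <- simulateTISeries(ff, truth15T(), protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  th <- computeThetaMap(ff)
  g <- angularProfile2D(sim$truthT1, th, fiberFA(ff),
                        faEdges = c(0, 1), binWidth = 9)
  p <- angularProfile1D(sim$truthT1, th, NULL, 9, "t1")
  expect_equal(as.vector(g@mean[1, ]), p@mean)
  expect_equal(as.vector(binCounts(g)[1, ]), as.integer(binCounts(p)))
})

test_that("FA rows agree when the quantity is FA-independent", {
  ff <- sampleFiberField(c(24, 24, 24), faRangeHigh = c(0.5, 0.8),
                         faRangeLow = c(0.2, 0.5), fracHigh = 0.5, seed = 21)
  sim <- simulateTISeries(ff, truth15T(), protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  th <- computeThetaMap(ff)
  g <- angularProfile2D(sim$truthT1, th, fiberFA(ff),
                        faEdges = c(0.2, 0.5, 0.8), binWidth = 9)
  filled <- binCounts(g)[1, ] > 30 & binCounts(g)[2, ] > 30
  expect_gt(sum(filled), 6)
  expect_lt(max(abs(g@mean[1, filled] - g@mean[2, filled])), 3)
})

test_that("empty 2-D cells are flagged with NA means and zero counts", {
  dims <- c(2, 1, 1)
  th <- new("ThetaMap", theta = array(c(5, 6), dims),
            validMask = array(TRUE, dims))
  g <- angularProfile2D(array(1, dims), th, array(0.3, dims),
                        faEdges = c(0.2, 0.4, 0.8), binWidth = 9)
  expect_identical(binCounts(g)[1, 1], 2L)
  expect_identical(binCounts(g)[2, 1], 0L)
  expect_true(is.na(g@mean[2, 1]))
})

test_that("large-TI signal profiles mirror the T1 profile inversely", {
  ff <- sampleFiberField(c(16, 16, 16), fracHigh = 1, seed = 25)
  sim <- simulateTISeries(ff, truth15T(), protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  th <- computeThetaMap(ff)
  ps <- tiSignalProfiles(sim$series, th)
  pT1 <- angularProfile1D(sim$truthT1, th, NULL, 9, "t1")
  s3000 <- ps[["3000"]]
  expect_lt(cor(s3000@mean, pT1@mean), -0.99)
  expect_match(quantityLabel(s3000), "ti_signal:3000")
})

test_that("two-pool signal humps appear only below 600 ms TI", {
  tp <- twoPoolModel(t1Short = 120, t1Long = 564)
  ff <- sampleFiberField(c(20, 20, 20), fracHigh = 1, seed = 33)
  sim <- simulateTISeries(ff, tp, protocolPreset("1.5T"),
                          noise = noiseSpec("rician", sigma = 20, seed = 34))
  th <- computeThetaMap(ff)
  ps <- tiSignalProfiles(sim$series, th)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    h <- profileHump(p)
    sem <- stats::median(p@sd / sqrt(binCounts(p)), na.rm = TRUE)
    visible <- h$amplitude > 3 * sem
    if (as.numeric(nm) < 600) {
      if (as.numeric(nm) < 200) expect_true(visible)
    } else {
      expect_false(visible)
    }
  }
})

test_that("zero series give zero profiles", {
  dims <- c(4, 4, 4)
  proto <- protocolPreset("1.5T")
  ser <- tiSeries(array(0, dim = c(dims, 6)), proto)
  th <- computeThetaMap(constantFiberField(dims))
  ps <- tiSignalProfiles(ser, th)
  expect_true(all(vapply(ps, function(p) {
    all(p@mean[binCounts(p) > 0] == 0)
  }, logical(1))))
})
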