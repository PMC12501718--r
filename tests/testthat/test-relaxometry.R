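test_that("the signed IR signal obeys its closed-form limits", {
  expect_equal(irSignal(1000, -2000, 564.1, 0), -1000)
  expect_lt(abs(irSignal(1000, -2000, 564.1, 564.1 * log(2))), 1e-9)
  expect_lt(abs(irSignal(1000, -2000, 808, 10 * 808) - 1000), 0.1)
  expect_error(irSignal(1000, -2000, -5, 100), "t1")
  expect_error(irSignal(1000, -2000, 500, -1), "ti")
})

test_that("polarity-restored fitting inverts a noiseless forward series", {
  ti <- c(200, 400, 700, 1100, 1800, 3000)
  y <- abs(irSignal(1000, -1960, 808, ti))
  f <- fitVoxelIR(y, ti)
  expect_true(f$ok)
  expect_rel_equal(f$t1, 808, 1e-3)
  expect_rel_equal(f$a, 1000, 1e-3)
  expect_rel_equal(f$b, -1960, 1e-3)
})

test_that("all-positive series need no flip and match the plain fit", {
  ti <- c(1500, 2200, 3000, 4000, 5000, 6500)  # far beyond the null point
  y <- irSignal(1000, -1960, 700, ti)
  expect_true(all(y > 0))
  f <- fitVoxelIR(y, ti, mode = "all")
  expect_identical(f$nflip, 0L)
  plain <- fitVoxelIR(y, ti, mode = "long")  # no restoration by definition
  # mode long keeps only 4 samples; compare against an unrestored 6-point
  # least-squares fit via the brute-force oracle at boundary 0
  bf <- bruteForcePolarityFit(y, ti)
  expect_identical(bf$nflip, 0L)
  expect_rel_equal(f$t1, bf$t1, 1e-4)
  expect_true(plain$ok)
})

test_that("exactly the pre-null samples are flipped and win the SSE race", {
  ti <- c(200, 400, 700, 1100, 1800, 3000)
  y <- abs(irSignal(1000, -1960, 808, ti))  # null at 808*log(1.96) = 544 ms
  expect_identical(sum(ti < 808 * log(1.96)), 2L)
  f <- fitVoxelIR(y, ti)
  expect_identical(f$nflip, 2L)
  bf <- bruteForcePolarityFit(y, ti)
  expect_identical(bf$nflip, 2L)
  others <- bf$sseByBoundary[names(bf$sseByBoundary) != "2"]
  expect_true(all(others > bf$sseByBoundary[["2"]] + 1e-6 * sum(y^2)))
})

test_that("fit SSE matches the brute-force oracle on noisy series", {
  set.seed(17)
  ti <- c(170, 340, 650, 1200, 2000, 3000)
  for (rep in 1:25) {
    a <- runif(1, 500, 2000)
    t1 <- runif(1, 250, 1500)
    eta <- runif(1, 0.85, 1)
    s <- irSignal(a, -(1 + eta) * a, t1, ti)
    y <- sqrt((s + rnorm(6, sd = a / 50))^2 + rnorm(6, sd = a / 50)^2)
    f <- fitVoxelIR(y, ti, checkGlobal = TRUE)
    bf <- bruteForcePolarityFit(y, ti)
    cands <- fiberT1:::polarityCandidates(y)
    sseCand <- min(bf$sseByBoundary[as.character(cands)])
    expect_lt(abs(f$sse - sseCand), 1e-4 * sseCand + 1e-9 * sum(y^2))
    expect_true(is.logical(f$globalInCandidates))
  }
})

test_that("fits are scale equivariant", {
  ti <- c(170, 340, 650, 1200, 2000, 3000)
  set.seed(23)
  s <- irSignal(1000, -1960, 620, ti)
  y <- sqrt((s + rnorm(6, sd = 20))^2 + rnorm(6, sd = 20)^2)
  f1 <- fitVoxelIR(y, ti)
  for (c in c(0.01, 7, 1500)) {
    f2 <- fitVoxelIR(c * y, ti)
    expect_rel_equal(f2$t1, f1$t1, 1e-5)
    expect_rel_equal(f2$a, c * f1$a, 1e-5)
    expect_rel_equal(f2$sse, c^2 * f1$sse, 1e-4)
  }
})

test_that("T1 recovery under Rician noise is unbiased to within 2 percent", {
  ti <- c(200, 390, 740, 1300, 2100, 3000)
  nvox <- 1000
  a <- 1000
  sigma <- a / 50
  t1true <- 808
  set.seed(99)
  s <- irSignal(a, -1.96 * a, t1true, ti)
  Y <- sqrt(sweep(matrix(rnorm(nvox * 6, sd = sigma), nvox), 2, s, "+")^2 +
              matrix(rnorm(nvox * 6, sd = sigma), nvox)^2)
  t1hat <- vapply(seq_len(nvox),
                  function(v) fitVoxelIR(Y[v, ], ti)$t1, numeric(1))
  err <- t1hat - t1true
  bias <- mean(err)
  rmse <- sqrt(mean(err^2))
  cat(sprintf("\n  [T1 recovery @ SNR 50] bias %.2f ms, RMSE %.2f ms\n",
              bias, rmse))
  expect_rel_equal(median(t1hat), t1true, 0.02)
})

test_that("map fitting matches across modes and respects masks", {
  ff <- sampleFiberField(c(6, 6, 6), fracHigh = 1, seed = 8)
  sim <- simulateTISeries(ff, truth15T(), protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  fAll <- fitT1Map(sim$series, mode = "all")
  fLong <- fitT1Map(sim$series, mode = "long")
  ok <- successMask(fAll) & successMask(fLong)
  expect_gt(mean(ok), 0.99)
  expect_lt(max(abs(t1Map(fAll)[ok] - t1Map(fLong)[ok]) / t1Map(fAll)[ok]),
            1e-4)
  # R1 is exactly the reciprocal on successful voxels
  expect_equal(r1Map(fAll)[ok], 1000 / t1Map(fAll)[ok])
  # boundary map only defined for the polarity-restored mode
  expect_true(all(is.na(polarityBoundaryMap(fLong))))
  expect_false(anyNA(polarityBoundaryMap(fAll)[ok]))

  empty <- fitT1Map(sim$series, mask = array(FALSE, dim = c(6, 6, 6)))
  expect_false(any(successMask(empty)))

  expect_error(fitT1Map(sim$series, mask = array(TRUE, dim = c(2, 2, 2))),
               "mask")
})

test_that("long-TI fits exceed all-TI fits in a noiseless two-pool phantom", {
  tp <- twoPoolModel(t1Short = 120, t1Long = 564)
  ff <- sampleFiberField(c(10, 10, 10), fracHigh = 1, seed = 13)
  sim <- simulateTISeries(ff, tp, protocolPreset("1.5T"),
                          noise = noiseSpec("none"))
  fAll <- fitT1Map(sim$series, mode = "all")
  fLong <- fitT1Map(sim$series, mode = "long")
  th <- thetaDegrees(computeThetaMap(ff))
  humpRegion <- th > 25 & th < 55 & successMask(fAll) & successMask(fLong)
  expect_gt(sum(humpRegion), 50)
  frac <- mean(t1Map(fLong)[humpRegion] >= t1Map(fAll)[humpRegion])
  expect_gte(frac, 0.95)
})

test_that("degenerate voxels fail gracefully", {
  ti <- c(170, 340, 650, 1200, 2000, 3000)
  f <- fitVoxelIR(rep(0, 6), ti)
  expect_false(f$ok)
  expect_true(is.na(f$t1))
  expect_error(fitVoxelIR(c(1, 2, 3), ti[1:3]), "4 samples")
})
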