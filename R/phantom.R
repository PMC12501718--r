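#' Construct a FiberField from arrays
#'
#' @param v1 4-D array `(nx, ny, nz, 3)` of per-voxel direction vectors.
#' @param fa 3-D array of fractional anisotropy values.
#' @return a [FiberField-class].
#' @export
fiberField <- function(v1, fa) new("FiberField", v1 = v1, fa = fa)

#' Construct a TISeries from an array and protocol
#'
#' @param data 4-D array `(nx, ny, nz, nTI)` of magnitude volumes.
#' @param protocol an [AcquisitionProtocol-class].
#' @param pixdim voxel size, mm (length 3).
#' @return a [TISeries-class].
#' @export
tiSeries <- function(data, protocol, pixdim = c(1, 1, 1)) {
  new("TISeries", data = data, protocol = protocol,
      pixdim = as.numeric(pixdim))
}

#' Sample a synthetic fiber field
#'
#' Draws a per-voxel fiber direction uniformly on the sphere (antipodal
#' pairs are equivalent; the hemisphere sign is left random to exercise the
#' downstream angle folding) and a fractional anisotropy value from one of
#' two uniform ranges: a fraction `fracHigh` of voxels receives FA from
#' `faRangeHigh` (coherent single-fiber white matter), the rest from
#' `faRangeLow`.
#'
#' @param gridShape integer length-3 grid dimensions.
#' @param faRangeHigh,faRangeLow FA intervals within \[0, 1\].
#' @param fracHigh fraction of voxels drawn from `faRangeHigh`.
#' @param seed integer RNG seed.
#' @return a [FiberField-class].
#' @examples
#' ff <- sampleFiberField(c(8, 8, 8), seed = 1)
#' range(fiberFA(ff))
#' @export
sampleFiberField <- function(gridShape, faRangeHigh = c(0.5, 0.8),
                             faRangeLow = c(0.2, 0.5), fracHigh = 0.6,
                             seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(gridShape < 1L)) {
    stop("gridShape must be three dimensions >= 1")
  }
  checkRange <- function(r, nm) {
    if (length(r) != 2L || r[1] < 0 || r[2] > 1 || r[1] > r[2]) {
      stop(sprintf("%s must be an interval within [0, 1]", nm))
    }
  }
  checkRange(faRangeHigh, "faRangeHigh")
  checkRange(faRangeLow, "faRangeLow")
  if (fracHigh < 0 || fracHigh > 1) stop("fracHigh must lie in [0, 1]")

  nvox <- prod(gridShape)
  set.seed(as.integer(seed))
  # isotropic Gaussian -> uniform direction on the sphere
  g <- matrix(stats::rnorm(3 * nvox), ncol = 3)
  nrm <- sqrt(rowSums(g^2))
  # guard against the measure-zero degenerate draw
  bad <- nrm < 1e-12
  if (any(bad)) {
    g[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)), ncol = 3, byrow = TRUE)
    nrm[bad] <- 1
  }
  g <- g / nrm

  high <- stats::runif(nvox) < fracHigh
  fa <- numeric(nvox)
  fa[high] <- stats::runif(sum(high), faRangeHigh[1], faRangeHigh[2])
  fa[!high] <- stats::runif(sum(!high), faRangeLow[1], faRangeLow[2])

  v1 <- array(g, dim = c(gridShape, 3L))
  fiberField(v1 = v1, fa = array(fa, dim = gridShape))
}

#' Simulate a magnitude TI series from a fiber field and ground truth
#'
#' Forward model of the inversion-recovery experiment inverted by
#' [fitT1Map()]. Per voxel, the fiber-to-field angle theta is computed from
#' the direction vector and the protocol's B0 direction; the true T1(theta)
#' comes from the ground-truth model; the signed recovery is
#' \deqn{s(TI) = a + b\,e^{-TI/T_1},\qquad b = -(1+\eta)\,a}
#' with inversion efficiency eta. For a [TwoPoolModel-class] the inverted
#' term is the fraction-weighted sum of the short- and long-compartment
#' recoveries sharing the same equilibrium amplitude `a`. Magnitude is taken
#' after (optionally) adding complex Gaussian noise, which makes the noise
#' Rician.
#'
#' @param fiber a [FiberField-class].
#' @param truth an [AngularT1Model-class] or [TwoPoolModel-class].
#' @param protocol an [AcquisitionProtocol-class].
#' @param amplitude equilibrium signal amplitude `a` (signal units).
#' @param invEfficiency inversion efficiency eta in (0, 1]; imperfect
#'   adiabatic inversion (default 0.96). Cancels in the T1 estimate.
#' @param noise a [NoiseSpec-class].
#' @return list with components `series` (a [TISeries-class]), `truthT1`
#'   (3-D array of ground-truth T1; the long-compartment T1 for a two-pool
#'   model), `theta` (3-D array of true fiber-to-field angles, degrees) and,
#'   for two-pool truth, `fractionShort` (3-D array).
#' @examples
#' ff <- sampleFiberField(c(6, 6, 6), seed = 2)
#' tr <- angularT1Model(t1Parallel = 537)
#' sim <- simulateTISeries(ff, tr, protocolPreset("1.5T"),
#'                         noise = noiseSpec("none"))
#' dim(seriesData(sim$series))
#' @export
simulateTISeries <- function(fiber, truth, protocol, amplitude = 1000,
                             invEfficiency = 0.96,
                             noise = noiseSpec("rician", sigma = amplitude / 50)) {
  stopifnot(is(fiber, "FiberField"), is(protocol, "AcquisitionProtocol"),
            is(noise, "NoiseSpec"))
  if (invEfficiency <= 0 || invEfficiency > 1) {
    stop("invEfficiency must lie in (0, 1]")
  }
  dims <- dim(fiber@fa)
  nvox <- prod(dims)
  ti <- protocol@tiList
  nTI <- length(ti)

  v <- matrix(fiber@v1, nrow = nvox, ncol = 3L)
  b0 <- protocol@b0Direction
  cosang <- abs(v %*% b0) / sqrt(rowSums(v^2))
  cosang[!is.finite(cosang)] <- NA_real_
  theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi

  b <- -(1 + invEfficiency) * amplitude
  signal <- matrix(0, nrow = nvox, ncol = nTI)
  if (is(truth, "AngularT1Model")) {
    t1true <- predictT1(truth, theta)
    for (k in seq_len(nTI)) {
      signal[, k] <- amplitude + b * exp(-ti[k] / t1true)
    }
    fshort <- NULL
  } else if (is(truth, "TwoPoolModel")) {
    fshort <- shortFraction(truth, theta)
    t1true <- rep(truth@t1Long, nvox)
    for (k in seq_len(nTI)) {
      rec <- fshort * exp(-ti[k] / truth@t1Short) +
        (1 - fshort) * exp(-ti[k] / truth@t1Long)
      signal[, k] <- amplitude + b * rec
    }
  } else {
    stop("truth must be an AngularT1Model or a TwoPoolModel")
  }

  if (noise@model == "rician" && noise@sigma > 0) {
    if (!is.na(noise@seed)) set.seed(noise@seed)
    n1 <- matrix(stats::rnorm(nvox * nTI, sd = noise@sigma), nrow = nvox)
    n2 <- matrix(stats::rnorm(nvox * nTI, sd = noise@sigma), nrow = nvox)
    signal <- sqrt((signal + n1)^2 + n2^2)
  } else {
    signal <- abs(signal)
  }

  out <- list(
    series = tiSeries(array(signal, dim = c(dims, nTI)), protocol),
    truthT1 = array(t1true, dim = dims),
    theta = array(theta, dim = dims)
  )
  if (!is.null(fshort)) out$fractionShort <- array(fshort, dim = dims)
  out
}
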