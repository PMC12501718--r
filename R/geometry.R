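#' Compute a fiber-to-field angle map
#'
#' The fiber-to-field angle is
#' `theta = acos(|v1 . b0|)` in degrees; the absolute value of the dot
#' product folds the antipodal sign ambiguity of the principal eigenvector
#' into \[0, 90\] degrees. Voxels whose direction vector norm deviates from
#' 1 by more than 1e-3 (including zero vectors outside the brain) are
#' marked invalid and excluded from downstream profiles.
#'
#' @param fiber a [FiberField-class].
#' @param b0Direction unit 3-vector, direction of B0 in grid coordinates
#'   (default: the third grid axis).
#' @return a [ThetaMap-class].
#' @examples
#' v1 <- array(0, c(1, 1, 2, 3)); v1[1, 1, 1, 3] <- 1; v1[1, 1, 2, 1] <- 1
#' fa <- array(0.7, c(1, 1, 2))
#' thetaDegrees(computeThetaMap(fiberField(v1, fa)))  # 0 and 90
#' @export
computeThetaMap <- function(fiber, b0Direction = c(0, 0, 1)) {
  stopifnot(is(fiber, "FiberField"))
  b0 <- as.numeric(b0Direction)
  nb <- sqrt(sum(b0^2))
  if (nb < 1e-12) stop("b0Direction must be a non-zero vector")
  if (abs(nb - 1) > 1e-9) stop("b0Direction must be a unit vector")
  dims <- dim(fiber@fa)
  v <- matrix(fiber@v1, nrow = prod(dims), ncol = 3L)
  nrm <- sqrt(rowSums(v^2))
  valid <- abs(nrm - 1) <= 1e-3
  cosang <- abs(as.vector(v %*% b0))
  theta <- rep(NA_real_, length(nrm))
  theta[valid] <- acos(pmin(1, cosang[valid] / nrm[valid])) * 180 / pi
  new("ThetaMap", theta = array(theta, dim = dims),
      validMask = array(valid, dim = dims))
}

#' FA-range mask
#'
#' Logical volume selecting voxels with `faLow < FA <= faHigh`. The lower
#' bound is strict, matching the convention "FA > 0.5" used to select
#' coherent single-fiber white matter; the upper bound is closed.
#'
#' @param fiber a [FiberField-class].
#' @param faLow,faHigh bounds with `0 <= faLow < faHigh <= 1`.
#' @return logical 3-D array.
#' @examples
#' ff <- sampleFiberField(c(6, 6, 6), seed = 4)
#' sum(faMask(ff, 0.5, 0.8))
#' @export
faMask <- function(fiber, faLow = 0.5, faHigh = 0.8) {
  stopifnot(is(fiber, "FiberField"))
  if (!(faLow >= 0 && faLow < faHigh && faHigh <= 1)) {
    stop("need 0 <= faLow < faHigh <= 1")
  }
  fiber@fa > faLow & fiber@fa <= faHigh
}

#' Downsample a volume by block averaging
#'
#' Non-overlapping block mean over `factor^3` blocks, used to bring
#' high-resolution images to the voxel size of a lower-resolution
#' acquisition before comparing angular profiles. Trailing partial blocks
#' are averaged over the voxels available.
#'
#' @param vol 3-D numeric array.
#' @param factor integer >= 1 (`1` is the identity).
#' @return 3-D array of dimensions `ceiling(dim(vol) / factor)`. A
#'   `pixdim` attribute, if present on `vol`, is scaled by `factor`.
#' @examples
#' downsampleVolume(array(0:7, c(2, 2, 2)), 2)  # 3.5
#' @export
downsampleVolume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  d <- dim(vol)
  if (length(d) != 3L) stop("vol must be a 3-D array")
  if (any(d < factor)) stop("each dimension must be >= factor")
  if (factor == 1L) return(vol)
  bx <- (seq_len(d[1]) - 1L) %/% factor
  by <- (seq_len(d[2]) - 1L) %/% factor
  bz <- (seq_len(d[3]) - 1L) %/% factor
  nd <- c(max(bx), max(by), max(bz)) + 1L
  grp <- as.vector(outer(outer(bx, by * nd[1], `+`), bz * nd[1] * nd[2], `+`))
  sums <- rowsum(as.vector(vol), grp)
  cnts <- rowsum(rep(1, length(grp)), grp)
  out <- array(as.vector(sums / cnts), dim = nd)
  pd <- attr(vol, "pixdim")
  if (!is.null(pd)) attr(out, "pixdim") <- pd * factor
  out
}
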