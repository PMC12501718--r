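# Bin index in 1..nbins for angles in [0, 90]; the last bin is closed at 90.
thetaBinIndex <- function(theta, binWidth) {
  nbins <- as.integer(round(90 / binWidth))
  pmin(floor(theta / binWidth) + 1L, nbins)
}

#' 1-D angular profile of a voxel-wise quantity
#'
#' Bins a scalar volume against the fiber-to-field angle: per bin
#' `[k*w, (k+1)*w)` (last bin closed at 90 degrees) the mean, standard
#' deviation and count over the voxels that are inside `mask`, have a valid
#' angle and a finite value. The default 9-degree bins give centers 4.5,
#' 13.5, ..., 85.5 degrees.
#'
#' @param values 3-D numeric array (e.g. `t1Map(fit)` or `r1Map(fit)`; NA
#'   values - unsuccessful fits - are excluded).
#' @param theta a [ThetaMap-class].
#' @param mask logical volume; NULL selects every voxel.
#' @param binWidth degrees; must divide 90.
#' @param quantityLabel label stored in the profile.
#' @return an [AngularProfile-class].
#' @examples
#' ff <- sampleFiberField(c(8, 8, 8), seed = 5)
#' th <- computeThetaMap(ff)
#' p <- angularProfile1D(thetaDegrees(th), th, quantityLabel = "theta")
#' as.data.frame(p)
#' @export
angularProfile1D <- function(values, theta, mask = NULL, binWidth = 9,
                             quantityLabel = "t1") {
  stopifnot(is(theta, "ThetaMap"))
  dims <- dim(theta@theta)
  if (!identical(dim(values), dims)) stop("values/theta shape mismatch")
  if (abs(90 / binWidth - round(90 / binWidth)) > 1e-9) {
    stop("binWidth must divide 90 degrees")
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dims)
  } else if (!identical(dim(mask), dims)) {
    stop("mask/theta shape mismatch")
  }
  nbins <- as.integer(round(90 / binWidth))
  centers <- (seq_len(nbins) - 0.5) * binWidth

  sel <- as.vector(mask) & as.vector(theta@validMask) &
    is.finite(as.vector(values))
  th <- as.vector(theta@theta)[sel]
  v <- as.vector(values)[sel]
  if (!length(v)) {
    warning("no voxels selected; profile is empty")
    return(new("AngularProfile", binWidth = binWidth, binCenters = centers,
               mean = rep(NA_real_, nbins), sd = rep(NA_real_, nbins),
               n = rep(0L, nbins), quantityLabel = quantityLabel))
  }
  bin <- thetaBinIndex(th, binWidth)
  n <- tabulate(bin, nbins)
  s <- as.vector(rowsum(v, bin, reorder = TRUE))
  present <- sort(unique(bin))
  mu <- rep(NA_real_, nbins)
  mu[present] <- s / n[present]
  sq <- rep(NA_real_, nbins)
  sq[present] <- as.vector(rowsum(v^2, bin, reorder = TRUE))
  sd <- rep(NA_real_, nbins)
  has2 <- n >= 2L
  sd[has2] <- sqrt(pmax(0, (sq[has2] - n[has2] * mu[has2]^2) / (n[has2] - 1)))
  new("AngularProfile", binWidth = binWidth, binCenters = centers,
      mean = mu, sd = sd, n = as.integer(n), quantityLabel = quantityLabel)
}

#' 2-D angle-by-FA grid of a voxel-wise quantity
#'
#' Cell means over joint membership in a fiber-to-field angle bin and an FA
#' interval `(e_k, e_{k+1}]` (left-open, right-closed, consistent with
#' [faMask()]). Empty cells carry NA means.
#'
#' @param values 3-D numeric array.
#' @param theta a [ThetaMap-class].
#' @param fa 3-D array of FA values.
#' @param faEdges ascending FA bin edges within \[0, 1\].
#' @param binWidth theta bin width, degrees.
#' @param quantityLabel label stored in the grid.
#' @return an [Angular2DGrid-class].
#' @export
angularProfile2D <- function(values, theta, fa, faEdges = seq(0.2, 0.8, 0.1),
                             binWidth = 9, quantityLabel = "t1") {
  stopifnot(is(theta, "ThetaMap"))
  dims <- dim(theta@theta)
  if (!identical(dim(values), dims) || !identical(dim(fa), dims)) {
    stop("values/fa/theta shape mismatch")
  }
  if (any(diff(faEdges) <= 0)) stop("faEdges must be ascending")
  nbins <- as.integer(round(90 / binWidth))
  centers <- (seq_len(nbins) - 0.5) * binWidth
  nfa <- length(faEdges) - 1L

  sel <- as.vector(theta@validMask) & is.finite(as.vector(values))
  th <- as.vector(theta@theta)[sel]
  v <- as.vector(values)[sel]
  f <- as.vector(fa)[sel]
  tb <- thetaBinIndex(th, binWidth)
  fb <- findInterval(f, faEdges, left.open = TRUE)  # (e_k, e_{k+1}] -> k
  keep <- fb >= 1L & fb <= nfa
  tb <- tb[keep]; fb <- fb[keep]; v <- v[keep]

  mu <- matrix(NA_real_, nrow = nfa, ncol = nbins)
  cnt <- matrix(0L, nrow = nfa, ncol = nbins)
  if (length(v)) {
    cell <- (tb - 1L) * nfa + fb
    s <- rowsum(v, cell, reorder = TRUE)
    k <- rowsum(rep(1L, length(v)), cell, reorder = TRUE)
    ids <- as.integer(rownames(s))
    cnt[ids] <- as.integer(k)
    mu[ids] <- s / k
  }
  new("Angular2DGrid", binCenters = centers, binWidth = binWidth,
      faEdges = as.numeric(faEdges), mean = mu, n = cnt,
      quantityLabel = quantityLabel)
}

#' Per-TI signal angular profiles
#'
#' Applies [angularProfile1D()] to each magnitude TI volume of a series;
#' labels carry the TI value (`"ti_signal:<TI>"`). These profiles expose
#' which inversion times carry the 40-degree feature: species with short T1
#' have fully relaxed before long TIs, so the hump disappears from long-TI
#' signal profiles at low field.
#'
#' @param series a [TISeries-class].
#' @param theta a [ThetaMap-class].
#' @param mask logical volume or NULL.
#' @param binWidth degrees.
#' @return named list of [AngularProfile-class], one per TI.
#' @export
tiSignalProfiles <- function(series, theta, mask = NULL, binWidth = 9) {
  stopifnot(is(series, "TISeries"))
  ti <- series@protocol@tiList
  dims <- dim(series@data)[1:3]
  out <- vector("list", length(ti))
  names(out) <- format(ti, trim = TRUE)
  for (k in seq_along(ti)) {
    vol <- array(series@data[, , , k], dim = dims)
    out[[k]] <- angularProfile1D(vol, theta, mask = mask,
                                 binWidth = binWidth,
                                 quantityLabel = paste0("ti_signal:", ti[k]))
  }
  out
}
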