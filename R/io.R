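#' Write / read scalar volumes as NIfTI
#'
#' Thin wrappers around RNifti. World coordinates beyond the voxel size are
#' not interpreted: all inputs of the pipeline are assumed co-registered on
#' identical grids.
#'
#' @param vol 3-D (or 4-D) numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param pixdim voxel size in mm.
#' @return `writeVolume`: the path, invisibly. `readVolume`: the array with
#'   a `pixdim` attribute.
#' @export
writeVolume <- function(vol, path, pixdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(pixdim, length.out = length(dim(vol)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write a TI series to disk
#'
#' Writes either a single 4-D NIfTI (default) or one 3-D NIfTI per TI,
#' plus a JSON sidecar with the acquisition protocol.
#'
#' @param series a [TISeries-class].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @param fourD write one 4-D file (TRUE) or one file per TI (FALSE).
#' @return character vector of the files written (sidecar last), invisibly.
#' @export
writeTISeries <- function(series, dir, prefix = "ti", fourD = TRUE) {
  stopifnot(is(series, "TISeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ti <- series@protocol@tiList
  files <- character(0)
  if (fourD) {
    f <- file.path(dir, paste0(prefix, "_series.nii.gz"))
    writeVolume(series@data, f, series@pixdim)
    files <- f
  } else {
    for (k in seq_along(ti)) {
      f <- file.path(dir, sprintf("%s_%04d.nii.gz", prefix, round(ti[k])))
      writeVolume(array(series@data[, , , k], dim = dim(series@data)[1:3]),
                  f, series@pixdim)
      files <- c(files, f)
    }
  }
  side <- file.path(dir, paste0(prefix, "_protocol.json"))
  p <- series@protocol
  jsonlite::write_json(
    list(fieldLabel = p@fieldLabel, tiList = p@tiList, tr = p@tr,
         readFlip = p@readFlip, b0Direction = p@b0Direction,
         pixdim = series@pixdim, fourD = fourD, files = basename(files)),
    side, auto_unbox = TRUE, digits = NA
  )
  invisible(c(files, side))
}

#' Read a TI series written by [writeTISeries()]
#'
#' @param sidecar path of the `*_protocol.json` sidecar.
#' @return a [TISeries-class].
#' @export
readTISeries <- function(sidecar) {
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  proto <- acquisitionProtocol(meta$fieldLabel, meta$tiList, meta$tr,
                               meta$readFlip, meta$b0Direction)
  dir <- dirname(sidecar)
  if (isTRUE(meta$fourD)) {
    dat <- readVolume(file.path(dir, meta$files[1]))
  } else {
    vols <- lapply(file.path(dir, meta$files), readVolume)
    dims <- dim(vols[[1]])
    dat <- array(unlist(vols), dim = c(dims, length(vols)))
  }
  tiSeries(array(as.numeric(dat), dim = dim(dat)), proto,
           pixdim = meta$pixdim)
}

#' Write / read a fiber field as NIfTI
#'
#' The direction vectors go to a 4-D 3-component file, FA to a 3-D file.
#'
#' @param fiber a [FiberField-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param pixdim voxel size, mm.
#' @return `writeFiberField`: the two paths (v1, fa), invisibly.
#' @export
writeFiberField <- function(fiber, dir, prefix = "dti", pixdim = c(1, 1, 1)) {
  stopifnot(is(fiber, "FiberField"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fv <- file.path(dir, paste0(prefix, "_v1.nii.gz"))
  ff <- file.path(dir, paste0(prefix, "_fa.nii.gz"))
  writeVolume(fiber@v1, fv, pixdim)
  writeVolume(fiber@fa, ff, pixdim)
  invisible(c(v1 = fv, fa = ff))
}

#' @rdname writeFiberField
#' @param v1Path,faPath paths of the V1 (4-D, 3 components) and FA volumes.
#' @export
readFiberField <- function(v1Path, faPath) {
  for (p in c(v1Path, faPath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  v1 <- readVolume(v1Path)
  fa <- readVolume(faPath)
  fiberField(array(as.numeric(v1), dim = dim(v1)),
             array(as.numeric(fa), dim = dim(fa)))
}

#' Write an angular profile (or list of profiles) as TSV
#'
#' Columns: `bin_center`, `mean`, `sd`, `n` (plus `quantity` when several
#' profiles are stacked).
#'
#' @param profile an [AngularProfile-class] or a list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  if (is(profile, "AngularProfile")) {
    df <- as.data.frame(profile)
  } else {
    df <- do.call(rbind, lapply(profile, function(p) {
      cbind(quantity = p@quantityLabel, as.data.frame(p))
    }))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write feature sets as a TSV table
#'
#' One row per feature set, mirroring the quantitative feature table
#' (endpoint difference, percent of mean, hump amplitude, percent, peak
#' angle, FWHM, mean value).
#'
#' @param featureSets an [AngularFeatureSet-class] or a list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeaturesTsv <- function(featureSets, path) {
  if (is(featureSets, "AngularFeatureSet")) featureSets <- list(featureSets)
  df <- do.call(rbind, lapply(featureSets, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
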