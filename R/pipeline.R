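#' Build a pipeline run configuration
#'
#' Collects every knob of the simulate-fit-bin-quantify pipeline in one
#' serialisable object. A run re-executed from its emitted configuration
#' and seed is bit-identical.
#'
#' @param field protocol preset label (`"1.5T"`, `"3T"`, `"7T"`); ignored
#'   when `protocol` is given.
#' @param protocol optional explicit [AcquisitionProtocol-class].
#' @param gridShape phantom grid dimensions (simulation mode).
#' @param truth ground-truth model ([AngularT1Model-class] or
#'   [TwoPoolModel-class]) for simulation mode.
#' @param inputs optional named list with paths `tiSidecar`, `v1`, `fa` for
#'   real-data mode (pre-registered volumes); when given, no simulation is
#'   performed and `truth`/`gridShape` are ignored.
#' @param faRange analysis FA window `(low, high]` (strict lower bound).
#' @param faRangeLow,fracHigh phantom FA mixture (see [sampleFiberField()]).
#' @param amplitude equilibrium signal amplitude.
#' @param snr amplitude-to-sigma ratio of the Rician noise; `Inf` or
#'   `noiseModel = "none"` disables noise.
#' @param noiseModel `"rician"` or `"none"`.
#' @param invEfficiency inversion efficiency.
#' @param binWidth angular bin width, degrees.
#' @param fitModes subset of `c("all", "long")`.
#' @param window hump search window, degrees.
#' @param extrapolate0,extrapolate90 endpoint conventions.
#' @param t1Bounds fit validity bounds, ms.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return a `fiberT1RunConfig` (a validated list).
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(field = "1.5T", protocol = NULL,
                      gridShape = c(32, 32, 32), truth = NULL,
                      inputs = NULL, faRange = c(0.5, 0.8),
                      faRangeLow = c(0.2, 0.5), fracHigh = 0.6,
                      amplitude = 1000, snr = 50, noiseModel = "rician",
                      invEfficiency = 0.96, binWidth = 9,
                      fitModes = c("all", "long"), window = c(20, 70),
                      extrapolate0 = TRUE, extrapolate90 = FALSE,
                      t1Bounds = c(100, 5000), seed = 1L) {
  if (is.null(protocol)) protocol <- protocolPreset(field)
  if (is.null(truth) && is.null(inputs)) {
    truth <- calibrateParallelT1(angularT1Model(500), 564.1)
  }
  fitModes <- match.arg(fitModes, c("all", "long"), several.ok = TRUE)
  cfg <- list(protocol = protocol, gridShape = as.integer(gridShape),
              truth = truth, inputs = inputs, faRange = faRange,
              faRangeLow = faRangeLow, fracHigh = fracHigh,
              amplitude = amplitude, snr = snr, noiseModel = noiseModel,
              invEfficiency = invEfficiency, binWidth = binWidth,
              fitModes = fitModes, window = window,
              extrapolate0 = extrapolate0, extrapolate90 = extrapolate90,
              t1Bounds = t1Bounds, seed = as.integer(seed))
  class(cfg) <- "fiberT1RunConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `readRunConfig`: a `fiberT1RunConfig`. `writeRunConfig`: the
#'   path, invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  proto <- NULL
  if (!is.null(y$protocol)) {
    proto <- acquisitionProtocol(
      y$protocol$fieldLabel %||% "custom",
      y$protocol$tiList,
      y$protocol$tr %||% 5000,
      y$protocol$readFlip %||% 4,
      unlist(y$protocol$b0Direction %||% c(0, 0, 1))
    )
  }
  truth <- NULL
  if (!is.null(y$truth)) {
    tt <- y$truth
    truth <- if (identical(tt$type, "two_pool")) {
      twoPoolModel(tt$t1Short %||% 120, tt$t1Long %||% 564,
                   tt$fractionShortBaseline %||% 0.2,
                   tt$fractionShortHumpAmplitude %||% -0.12,
                   tt$humpCenter %||% 40, tt$humpFwhm %||% 34)
    } else {
      m <- angularT1Model(tt$t1Parallel %||% 537, tt$delta090 %||% 27,
                          tt$humpAmplitude %||% 23.5, tt$humpCenter %||% 40,
                          tt$humpFwhm %||% 34)
      if (!is.null(tt$targetMean)) m <- calibrateParallelT1(m, tt$targetMean)
      m
    }
  }
  args <- y[setdiff(names(y), c("protocol", "truth"))]
  args <- args[names(args) %in% names(formals(runConfig))]
  args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
  do.call(runConfig, c(args, list(protocol = proto, truth = truth)))
}

#' @rdname readRunConfig
#' @param config a `fiberT1RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  p <- config$protocol
  y <- list(
    protocol = list(fieldLabel = p@fieldLabel, tiList = p@tiList, tr = p@tr,
                    readFlip = p@readFlip, b0Direction = p@b0Direction),
    truth = if (is(config$truth, "TwoPoolModel")) {
      t <- config$truth
      list(type = "two_pool", t1Short = t@t1Short, t1Long = t@t1Long,
           fractionShortBaseline = t@fractionShortBaseline,
           fractionShortHumpAmplitude = t@fractionShortHumpAmplitude,
           humpCenter = t@humpCenter, humpFwhm = t@humpFwhm)
    } else if (is(config$truth, "AngularT1Model")) {
      t <- config$truth
      list(type = "single_pool", t1Parallel = t@t1Parallel,
           delta090 = t@delta090, humpAmplitude = t@humpAmplitude,
           humpCenter = t@humpCenter, humpFwhm = t@humpFwhm)
    } else NULL
  )
  rest <- config[setdiff(names(config), c("protocol", "truth"))]
  yaml::write_yaml(c(y, rest), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stageError <- function(stage, msg) {
  stop(sprintf("stage '%s': %s", stage, msg), call. = FALSE)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stageError(stage, conditionMessage(e)))
}

#' Run the full angular-T1 pipeline
#'
#' Executes, in order: phantom simulation (or loading of pre-registered
#' real inputs), voxel-wise T1/R1 fitting for each requested mode,
#' fiber-to-field angle mapping, FA masking, angular binning of T1, R1 and
#' per-TI signals, and feature quantification. All artifacts (NIfTI
#' volumes, TSV profiles and feature tables, JSON sidecars) are written
#' under `outDir` together with a manifest carrying the configuration,
#' derived per-stage seeds and MD5 hashes of every output file. A failure
#' in any stage aborts with an error naming the stage.
#'
#' @param config a `fiberT1RunConfig` from [runConfig()].
#' @param outDir output directory.
#' @param writeVolumes write NIfTI volumes (disable to keep only tables).
#' @return invisibly, a list with the in-memory objects (`series`, `fiber`,
#'   `theta`, `mask`, `fits`, `profiles`, `features`), the per-mode feature
#'   data.frame `featureTable` and `manifestPath`.
#' @examples
#' cfg <- runConfig(gridShape = c(12, 12, 12), seed = 7, fitModes = "all")
#' res <- runPipeline(cfg, outDir = file.path(tempdir(), "demo"))
#' res$featureTable
#' @export
runPipeline <- function(config, outDir, writeVolumes = TRUE) {
  if (!inherits(config, "fiberT1RunConfig")) {
    stop("config must come from runConfig()")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, 2L)

  # --- stage: inputs (simulate or load) ---------------------------------
  sim <- NULL
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    fiber <- withStage("load_inputs", {
      for (nm in c("tiSidecar", "v1", "fa")) {
        if (is.null(inp[[nm]]) || !file.exists(inp[[nm]])) {
          stop(sprintf("missing input '%s' (%s)", nm,
                       inp[[nm]] %||% "unset"))
        }
      }
      readFiberField(inp$v1, inp$fa)
    })
    series <- withStage("load_inputs", readTISeries(inp$tiSidecar))
    if (!identical(dim(fiberFA(fiber)), dim(seriesData(series))[1:3])) {
      stageError("load_inputs",
                 "fiber field and TI series grids differ; inputs must be co-registered")
    }
  } else {
    fiber <- withStage("simulate", {
      sampleFiberField(config$gridShape, faRangeHigh = config$faRange,
                       faRangeLow = config$faRangeLow,
                       fracHigh = config$fracHigh, seed = childSeeds[1])
    })
    sim <- withStage("simulate", {
      sigma <- if (identical(config$noiseModel, "none") ||
                   !is.finite(config$snr)) 0 else config$amplitude / config$snr
      nm <- if (sigma > 0) "rician" else "none"
      simulateTISeries(fiber, config$truth, config$protocol,
                       amplitude = config$amplitude,
                       invEfficiency = config$invEfficiency,
                       noise = noiseSpec(nm, sigma = sigma,
                                         seed = childSeeds[2]))
    })
    series <- sim$series
  }

  # --- stage: theta map and mask ----------------------------------------
  theta <- withStage("theta_map", {
    computeThetaMap(fiber, config$protocol@b0Direction)
  })
  mask <- withStage("theta_map", {
    faMask(fiber, config$faRange[1], config$faRange[2])
  })

  # --- stage: fit -------------------------------------------------------
  fits <- list()
  for (mode in config$fitModes) {
    fits[[mode]] <- withStage(paste0("fit_", mode), {
      fitT1Map(series, mode = mode, mask = mask,
               t1Bounds = config$t1Bounds)
    })
  }

  # --- stage: profiles --------------------------------------------------
  profiles <- withStage("profiles", {
    out <- list()
    for (mode in names(fits)) {
      fit <- fits[[mode]]
      okMask <- mask & successMask(fit)
      out[[mode]] <- list(
        t1 = angularProfile1D(t1Map(fit), theta, okMask,
                              config$binWidth, "t1"),
        r1 = angularProfile1D(r1Map(fit), theta, okMask,
                              config$binWidth, "r1")
      )
    }
    out$tiSignal <- tiSignalProfiles(series, theta, mask, config$binWidth)
    out
  })

  # --- stage: features --------------------------------------------------
  features <- withStage("features", {
    out <- list()
    for (mode in names(fits)) {
      fit <- fits[[mode]]
      okMask <- mask & successMask(fit)
      meanT1 <- mean(t1Map(fit)[okMask])
      meanR1 <- mean(r1Map(fit)[okMask])
      out[[mode]] <- list(
        t1 = quantifyFeatures(profiles[[mode]]$t1, meanT1,
                              extrapolate0 = config$extrapolate0,
                              extrapolate90 = config$extrapolate90,
                              window = config$window),
        r1 = quantifyFeatures(profiles[[mode]]$r1, meanR1,
                              extrapolate0 = config$extrapolate0,
                              extrapolate90 = config$extrapolate90,
                              window = config$window)
      )
    }
    out
  })

  # --- stage: write artifacts ------------------------------------------
  files <- withStage("write", {
    fl <- character(0)
    if (writeVolumes) {
      fl <- c(fl, writeTISeries(series, outDir, prefix = "ti"))
      fl <- c(fl, writeFiberField(fiber, outDir, prefix = "dti"))
      fl <- c(fl, writeVolume(thetaDegrees(theta),
                              file.path(outDir, "theta.nii.gz")))
      if (!is.null(sim)) {
        fl <- c(fl, writeVolume(sim$truthT1,
                                file.path(outDir, "truth_t1.nii.gz")))
      }
      for (mode in names(fits)) {
        fit <- fits[[mode]]
        for (what in c("t1", "r1", "sse")) {
          vol <- switch(what, t1 = t1Map(fit), r1 = r1Map(fit),
                        sse = sseMap(fit))
          f <- file.path(outDir, sprintf("%s_map_%s.nii.gz", what, mode))
          fl <- c(fl, writeVolume(vol, f))
        }
        f <- file.path(outDir, sprintf("success_%s.nii.gz", mode))
        fl <- c(fl, writeVolume(successMask(fit) + 0, f))
      }
    }
    for (mode in names(fits)) {
      f <- file.path(outDir, sprintf("profile_t1_%s.tsv", mode))
      fl <- c(fl, writeProfileTsv(profiles[[mode]]$t1, f))
      f <- file.path(outDir, sprintf("profile_r1_%s.tsv", mode))
      fl <- c(fl, writeProfileTsv(profiles[[mode]]$r1, f))
      f <- file.path(outDir, sprintf("features_%s.tsv", mode))
      fl <- c(fl, writeFeaturesTsv(unname(features[[mode]]), f))
    }
    fl <- c(fl, writeProfileTsv(profiles$tiSignal,
                                file.path(outDir, "profile_ti_signal.tsv")))
    fl
  })

  featureTable <- do.call(rbind, lapply(names(features), function(mode) {
    cbind(mode = mode,
          do.call(rbind, lapply(unname(features[[mode]]), as.data.frame)))
  }))

  manifestPath <- file.path(outDir, "manifest.json")
  withStage("manifest", {
    cfgPath <- file.path(outDir, "run_config.yaml")
    writeRunConfig(config, cfgPath)
    files <- c(files, cfgPath)
    hashes <- as.vector(tools::md5sum(files))
    jsonlite::write_json(
      list(
        package = "fiberT1",
        version = as.character(utils::packageVersion("fiberT1")),
        seed = config$seed,
        childSeeds = childSeeds,
        stages = c("inputs", "theta_map",
                   paste0("fit_", config$fitModes), "profiles", "features",
                   "write"),
        files = data.frame(path = basename(files), md5 = hashes)
      ),
      manifestPath, auto_unbox = TRUE, digits = NA
    )
  })

  invisible(list(series = series, fiber = fiber, theta = theta, mask = mask,
                 sim = sim, fits = fits, profiles = profiles,
                 features = features, featureTable = featureTable,
                 manifestPath = manifestPath))
}
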