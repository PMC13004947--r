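## File formats, configuration and the end-to-end pipeline driver.
##
## Trajectory tables travel as CSV (um plus pixel columns at 0.108
## um/px); image stacks as multi-page TIFF in T-major page order with a
## JSON sidecar carrying shape, voxel size and intensity scale.

#' Read a trajectory table
#'
#' Requires columns `trajectory` and `frame` plus either `x`/`y` (um) or
#' `x_px`/`y_px` (pixels, converted with `pixelSize`). Frames must be
#' strictly increasing without gaps within each trajectory (the tracker
#' allows no blinking).
#'
#' @param path CSV path.
#' @param pixelSize um per pixel for pixel-unit files (default 0.108).
#' @return validated data.frame with `trajectory`, `frame`, `x`, `y`.
#' @export
readTrajectories <- function(path, pixelSize = 0.108) {
  df <- read.csv(path)
  if (!all(c("trajectory", "frame") %in% names(df)))
    stop("missing required columns: trajectory, frame")
  if (!all(c("x", "y") %in% names(df))) {
    if (all(c("x_px", "y_px") %in% names(df))) {
      df$x <- df$x_px * pixelSize
      df$y <- df$y_px * pixelSize
    } else stop("missing position columns (x/y or x_px/y_px)")
  }
  df <- df[order(df$trajectory, df$frame), ]
  same <- c(FALSE, diff(as.integer(factor(df$trajectory))) == 0)
  dfr <- c(NA, diff(df$frame))
  bad <- same & dfr != 1
  if (any(bad))
    stop("non-consecutive frames within trajectory(ies): ",
         paste(unique(df$trajectory[bad]), collapse = ", "))
  df[, c("trajectory", "frame", "x", "y")]
}

#' Write a trajectory table
#'
#' @param tracks data.frame with `trajectory`, `frame`, `x`, `y` (um).
#' @param path CSV path.
#' @param pixelSize um per pixel for the added `x_px`/`y_px` columns.
#' @return the path, invisibly.
#' @export
writeTrajectories <- function(tracks, path, pixelSize = 0.108) {
  tracks$x_px <- tracks$x / pixelSize
  tracks$y_px <- tracks$y / pixelSize
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Write a 4D image stack as multi-page TIFF
#'
#' Pages are stored T-major (all z of frame 1, then frame 2, ...) as
#' 32-bit float; intensities are scaled into \[0, 1\] for storage and the
#' scale recorded, with shape and voxel size, in a JSON sidecar at
#' `<path>.json`.
#'
#' @param stack 4D array (T, Z, Y, X).
#' @param path TIFF path.
#' @param voxelSize um per voxel (z, y, x).
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path, voxelSize = c(0.3, 0.108, 0.108)) {
  stopifnot(length(dim(stack)) == 4)
  d <- dim(stack)
  lo <- min(stack)
  scale <- max(max(stack) - lo, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1
    pages[[k]] <- (stack[t, z, , ] - lo) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(shape = d, voxelSize = voxelSize,
                            offset = lo, scale = scale, axes = "TZYX"),
                       paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a 4D image stack written by [writeStack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar (or an explicit
#'   `shape`) must declare the T/Z split, otherwise the axes are
#'   ambiguous and an error is raised.
#' @param shape optional integer (T, Z, Y, X) overriding the sidecar.
#' @return 4D array with attributes `voxelSize` and `depthUm` (Z extent
#'   times slice thickness).
#' @export
readStack <- function(path, shape = NULL) {
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  if (is.null(shape)) {
    if (is.null(meta)) stop("axis ambiguity: no sidecar metadata and no shape given")
    shape <- as.integer(meta$shape)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != shape[1] * shape[2])
    stop("page count does not match declared shape")
  scale <- if (!is.null(meta)) meta$scale else 1
  offset <- if (!is.null(meta) && !is.null(meta$offset)) meta$offset else 0
  voxelSize <- if (!is.null(meta)) as.numeric(meta$voxelSize)
               else c(0.3, 0.108, 0.108)
  out <- array(0, shape)
  k <- 0
  for (t in seq_len(shape[1])) for (z in seq_len(shape[2])) {
    k <- k + 1
    out[t, z, , ] <- pages[[k]] * scale + offset
  }
  attr(out, "voxelSize") <- voxelSize
  ## axial span between the first and last slice centers
  ## (64 slices at 300 nm -> 18.9 um)
  attr(out, "depthUm") <- (shape[2] - 1) * voxelSize[1]
  out
}

#' Default pipeline configuration
#'
#' Nested list holding every stage parameter, each printed constant of
#' the analysis appearing exactly once: the 0.108 um pixel, the
#' 0.001-100 um^2/s grid of 100 coefficients, the 0.2 um jump filter
#' and 30-degree angle windows, the 15-point / 0.2 um density
#' clustering with 30 control spots, the 1.65 enrichment threshold, the
#' 600 nm z tolerance, the 9 s sampling and 30 s burst minimum, and the
#' simulator constants (15 min ON, 2.5 kb/min, 2.8 kb, 5 um nucleus,
#' 15 nm molecule, 1 um gene region, 400 nm PSF, 50,000 molecules,
#' 0.1 s step).
#'
#' @param seed global seed; all stage seeds are derived from it.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = seed,
    pixelSize = 0.108,
    smt = list(
      frameInterval = 0.01, sigmaLoc = 0.030,
      grid = list(min = 0.001, max = 100, n = 100),
      nTrajectories = 3000, nFields = 8,
      stateD = c(0.002, 0.2, 8),
      conditions = list(
        vehicle = c(0.37, 0.33, 0.30),
        triptolide = c(0.142, 0.403, 0.455),
        amanitin = c(0.218, 0.367, 0.415))),
    anisotropy = list(minJump = 0.2, window = 30, bootFrac = 0.5,
                      nBoot = 20),
    clustering = list(eps = 0.2, minSamples = 15, controlsPerCluster = 30),
    imaging = list(enrichmentThreshold = 1.65, dogSigmaLow = 1,
                   dogSigmaHigh = 5, dogPercentile = 0.9995,
                   zTolerance = 0.6, frameInterval = 10,
                   voxelSize = c(0.3, 0.108, 0.108)),
    bursts = list(samplingInterval = 9, minDuration = 30,
                  smoothWindow = 3, discDiameterPx = 11,
                  spotDogSigmas = c(1.5, 6), spotMinVoxels = 6),
    simulator = list(tOn = 15, rElongation = 2.5, geneLength = 2.8,
                     nucleusDiameter = 5, moleculeDiameter = 15,
                     geneRegionDiameter = 1, psfFwhm = 400,
                     nTotalMolecules = 50000, projectionSlices = 3,
                     dt = 0.1))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [defaultRunConfig()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(defaultRunConfig(), user)
}

## md5 of an R object, via its serialization
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the synthetic SMT pipeline end-to-end
#'
#' Simulates vehicle-, triptolide- and amanitin-like trajectory sets,
#' fits occupancies, freezes state boundaries on the vehicle profile
#' (applied to the drug conditions), computes per-field fractions,
#' decomposes the vehicle bound fraction, and computes the
#' fold-anisotropy of non-bound vehicle trajectories. Returns the stage
#' outputs plus a provenance manifest (seeds, parameters, output
#' hashes).
#'
#' @param config configuration list, see [defaultRunConfig()].
#' @param stages subset of `c("simulate", "kinetics", "decompose",
#'   "anisotropy")`; dependencies must be included.
#' @param outputDir optional directory for CSV outputs.
#' @return list with per-stage results and `manifest`.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        stages = c("simulate", "kinetics", "decompose",
                                   "anisotropy"),
                        outputDir = NULL) {
  res <- list()
  need <- function(dep, stage) {
    if (!dep %in% stages)
      stop(sprintf("stage '%s' requires stage '%s'", stage, dep))
  }
  if ("simulate" %in% stages) {
    sm <- config$smt
    res$simulate <- lapply(names(sm$conditions), function(cond) {
      cfg <- smtSimConfig(
        nTrajectories = sm$nTrajectories,
        stateFractions = sm$conditions[[cond]],
        stateD = sm$stateD, frameInterval = sm$frameInterval,
        localizationSigma = sm$sigmaLoc,
        seed = deriveSeed(config$seed, paste0("smt-", cond)))
      simulateTrajectories(cfg)
    })
    names(res$simulate) <- names(sm$conditions)
  }
  if ("kinetics" %in% stages) {
    need("simulate", "kinetics")
    sm <- config$smt
    grid <- diffusionGrid(sm$grid$n, sm$grid$min, sm$grid$max)
    res$kinetics <- lapply(names(res$simulate), function(cond) {
      sim <- res$simulate[[cond]]
      prof <- estimateOccupancy(sim$tracks, grid, sm$sigmaLoc,
                                sm$frameInterval)
      list(profile = prof, D = assignTrajectoryD(prof))
    })
    names(res$kinetics) <- names(res$simulate)
    ## state boundaries frozen on the vehicle profile
    bins <- findStateBoundaries(res$kinetics$vehicle$profile)
    res$bins <- bins
    res$fractions <- lapply(names(res$kinetics), function(cond) {
      tracks <- res$simulate[[cond]]$tracks
      ids <- unique(tracks$trajectory)
      field <- setNames((as.integer(ids) - 1) %% sm$nFields,
                        as.character(ids))
      computeOccupancyFractions(tracks, field, bins, grid, sm$sigmaLoc,
                                sm$frameInterval)
    })
    names(res$fractions) <- names(res$kinetics)
  }
  if ("decompose" %in% stages) {
    need("kinetics", "decompose")
    fr <- res$fractions
    bname <- binLabels(res$bins)[1]
    res$decompose <- decomposeBoundFraction(
      fr$vehicle$mean[bname], fr$amanitin$mean[bname],
      fr$triptolide$mean[bname],
      fr$vehicle$sd[bname], fr$amanitin$sd[bname], fr$triptolide$sd[bname])
  }
  if ("anisotropy" %in% stages) {
    need("kinetics", "anisotropy")
    an <- config$anisotropy
    D <- res$kinetics$vehicle$D
    lab <- binLabels(res$bins)[binAssign(D, res$bins)]
    names(lab) <- names(D)
    ang <- computeAngles(res$simulate$vehicle$tracks, an$minJump,
                         stateLabels = lab)
    res$anisotropy <- list(
      angles = ang,
      fold = foldAnisotropy(ang, an$window),
      boot = bootstrapAnisotropy(ang, an$bootFrac, an$nBoot,
                                 deriveSeed(config$seed, "anisotropy-boot"),
                                 an$window))
  }
  manifest <- list(
    package = as.character(utils::packageVersion("polclust")),
    seed = config$seed,
    parameters = config,
    stages = stages,
    hashes = lapply(res[setdiff(names(res), "manifest")], objectHash))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$simulate))
      for (cond in names(res$simulate))
        writeTrajectories(res$simulate[[cond]]$tracks,
                          file.path(outputDir, paste0("tracks-", cond, ".csv")),
                          config$pixelSize)
    if (!is.null(res$fractions))
      for (cond in names(res$fractions))
        write.csv(res$fractions[[cond]]$perField,
                  file.path(outputDir, paste0("fractions-", cond, ".csv")),
                  row.names = FALSE)
    manifest$files <- tools::md5sum(list.files(outputDir, full.names = TRUE))
  }
  res$manifest <- manifest
  res
}
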