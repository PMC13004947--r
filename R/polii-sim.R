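## Stochastic promoter-loading simulator: Bernoulli loading and
## dissociation per time step, deterministic elongation, and rendering
## of microscope-like frames with a Gaussian PSF.

## fraction of the nuclear sphere volume inside the central projection
## slab (spherical-cap geometry, exact)
slabFraction <- function(config) {
  R <- config@nucleusDiameter / 2
  h <- min(config@projectionSlices * config@sliceThickness, 2 * R)
  (R^2 * h - h^3 / 12) * 3 / (4 * R^3)
}

## mass of a 2D Gaussian (sd sigma) centered at distance d from the
## center of a disc of radius rho
gaussMassInDisc <- function(d, rho, sigma) {
  stats::pchisq((rho / sigma)^2, df = 2, ncp = (d / sigma)^2)
}

#' Simulate polymerase loading, elongation and dissociation at one gene
#'
#' While the promoter is ON (the first `tOn` minutes), one polymerase is
#' loaded at position 0 with probability `kOn` per `dt` step. Each
#' engaged polymerase advances by `rElongation * dt`, dissociates with
#' probability `kOff` per step, and completes when its position reaches
#' the gene length, after which residual molecules run off. The event
#' ledger (loaded = completed + dissociated + engaged) balances at every
#' step.
#'
#' @param config a [PolIISimConfig-class] object.
#' @param duration total simulated time, s.
#' @return list with `time` (s, one per step), `engaged` (count per
#'   step), `ledger` (data.frame of cumulative loaded / dissociated /
#'   completed and current engaged per step), and `positions` (gene
#'   positions in kb of molecules engaged at the final step).
#' @export
simulateGene <- function(config, duration) {
  stopifnot(is(config, "PolIISimConfig"))
  validObject(config)
  if (duration < config@dt) stop("duration must be at least one step")
  set.seed(config@seed)
  dt <- config@dt
  nSteps <- floor(duration / dt)
  vStep <- config@rElongation / 60 * dt          # kb per step
  onSteps <- round(config@tOn * 60 / dt)
  pos <- numeric(0)
  engaged <- integer(nSteps)
  loaded <- dissociated <- completed <- integer(nSteps)
  cl <- cd <- cc <- 0L
  for (s in seq_len(nSteps)) {
    pos <- pos + vStep
    if (length(pos) && config@kOff > 0) {
      off <- runif(length(pos)) < config@kOff
      cd <- cd + sum(off)
      pos <- pos[!off]
    }
    done <- pos >= config@geneLength
    cc <- cc + sum(done)
    pos <- pos[!done]
    if (s <= onSteps && runif(1) < config@kOn) {
      pos <- c(pos, 0)
      cl <- cl + 1L
    }
    engaged[s] <- length(pos)
    loaded[s] <- cl; dissociated[s] <- cd; completed[s] <- cc
  }
  list(time = seq_len(nSteps) * dt, engaged = engaged,
       ledger = data.frame(time = seq_len(nSteps) * dt, loaded = loaded,
                           dissociated = dissociated, completed = completed,
                           engaged = engaged),
       positions = pos)
}

#' Render one microscope-like frame
#'
#' Background molecules (the nucleus-wide count scaled to the central
#' projection slab by exact spherical-cap geometry) are placed uniformly
#' in the projected nuclear disc and `nEngaged` gene-engaged molecules
#' at the gene locus (disc center); every molecule is rendered as a 2D
#' Gaussian of FWHM `psfFwhm` with unit integrated flux. The image is
#' padded by 4 PSF sigmas beyond the nuclear disc so no flux is clipped.
#'
#' @param config a [PolIISimConfig-class] object.
#' @param nEngaged number of gene-engaged molecules.
#' @param seed optional seed for the background placement.
#' @return numeric matrix (Y, X) in units of per-molecule flux, with
#'   attribute `pixelSize`.
#' @export
renderFrame <- function(config, nEngaged, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- config@psfFwhm / 1000 / (2 * sqrt(2 * log(2)))   # um
  R <- config@nucleusDiameter / 2
  half <- R + 4 * sigma
  px <- config@pixelSize
  npx <- ceiling(2 * half / px)
  ctr <- npx / 2 * px
  nBg <- round(config@nTotalMolecules * slabFraction(config))
  u <- runif(nBg); a <- runif(nBg)
  mx <- c(ctr + R * sqrt(u) * cos(2 * pi * a), rep(ctr, nEngaged > 0))
  my <- c(ctr + R * sqrt(u) * sin(2 * pi * a), rep(ctr, nEngaged > 0))
  wt <- c(rep(1, nBg), if (nEngaged > 0) nEngaged)
  img <- matrix(0, npx, npx)
  cent <- (seq_len(npx) - 0.5) * px
  hw <- ceiling(4 * sigma / px)
  norm <- px^2 / (2 * pi * sigma^2)
  for (i in seq_along(mx)) {
    iy <- max(1, floor(my[i] / px) - hw):min(npx, ceiling(my[i] / px) + hw)
    ix <- max(1, floor(mx[i] / px) - hw):min(npx, ceiling(mx[i] / px) + hw)
    gy <- exp(-(cent[iy] - my[i])^2 / (2 * sigma^2))
    gx <- exp(-(cent[ix] - mx[i])^2 / (2 * sigma^2))
    img[iy, ix] <- img[iy, ix] + wt[i] * norm * (gy %o% gx)
  }
  attr(img, "pixelSize") <- px
  img
}

#' Simulate an RNAPII enrichment trace at the gene region
#'
#' Runs [simulateGene()] and, at every subsample time, computes the
#' integrated signal in the 1 um gene-region disc analytically: each
#' molecule contributes the mass of its PSF falling inside the disc
#' (background molecules are re-placed uniformly in the projected
#' nuclear disc per frame; engaged molecules sit at the locus). Dividing
#' by the expected background integral in an equal disc gives the
#' enrichment trace, which is smoothed with the same centered moving
#' average used for experimental traces.
#'
#' @param config a [PolIISimConfig-class] object.
#' @param duration total simulated time, s.
#' @param smoothWindow moving-average window, samples (default 3).
#' @return list with `trace` (data.frame: `time`, `mcp` = engaged
#'   count, `rnapii` = enrichment, both smoothed), `raw` (unsmoothed),
#'   `bursts` (from [segmentBursts()]), and `sim` (the [simulateGene()]
#'   output).
#' @export
simulateTrace <- function(config, duration, smoothWindow = 3) {
  sim <- simulateGene(config, duration)
  dt <- config@dt
  ts <- seq(0, duration, by = config@subsampleInterval)
  idx <- pmin(length(sim$engaged), pmax(1, round(ts / dt)))
  eng <- ifelse(ts == 0, 0L, sim$engaged[idx])
  sigma <- config@psfFwhm / 1000 / (2 * sqrt(2 * log(2)))
  R <- config@nucleusDiameter / 2
  rho <- config@geneRegionDiameter / 2
  nBg <- round(config@nTotalMolecules * slabFraction(config))
  ## expected per-molecule disc mass for a uniformly placed molecule
  dg <- seq(0, R + 5 * sigma, length.out = 600)
  mg <- gaussMassInDisc(dg, rho, sigma)
  pd <- 2 * dg / R^2; pd[dg > R] <- 0
  em <- sum((mg * pd)[-1] * diff(dg))
  m0 <- gaussMassInDisc(0, rho, sigma)
  enr <- vapply(seq_along(ts), function(i) {
    u <- runif(nBg)
    d <- R * sqrt(u)                     # radial distance of bg molecules
    bgMass <- sum(gaussMassInDisc(d, rho, sigma))
    (bgMass + eng[i] * m0) / (nBg * em)
  }, numeric(1))
  raw <- data.frame(time = ts, mcp = eng, rnapii = enr)
  trace <- data.frame(time = ts,
                      mcp = movingAverage(eng, smoothWindow),
                      rnapii = movingAverage(enr, smoothWindow))
  bursts <- segmentBursts(trace, samplingInterval = config@subsampleInterval)
  list(trace = trace, raw = raw, bursts = bursts, sim = sim)
}

#' Sweep the loading probability and collect burst parameters
#'
#' Repeats [simulateTrace()] across `konValues`, recording per replicate
#' the loading rate and duration of the principal (longest) burst and
#' the maximum smoothed enrichment; a replicate is called detectable
#' when that maximum reaches `detectionThreshold` (default 1.65, the
#' imaging enrichment filter).
#'
#' @param konValues loading probabilities to scan.
#' @param config base [PolIISimConfig-class]; `kOn` and `seed` are
#'   overridden per run.
#' @param nReplicates replicates per value.
#' @param seed global seed (per-run seeds are derived from it).
#' @param duration simulated time, s; defaults to the ON time plus one
#'   traversal plus one minute.
#' @param detectionThreshold enrichment detectability cutoff.
#' @return data.frame: `kon`, `replicate`, `loadingRate`,
#'   `burstDuration`, `maxEnrichment`, `detectable`.
#' @export
sweepKon <- function(konValues, config = polIISimConfig(),
                     nReplicates = 5, seed = 1L, duration = NULL,
                     detectionThreshold = 1.65) {
  if (length(konValues) < 2) stop("need at least 2 kOn values")
  if (is.null(duration))
    duration <- config@tOn * 60 +
      config@geneLength / config@rElongation * 60 + 60
  out <- NULL
  for (kon in konValues) {
    for (r in seq_len(nReplicates)) {
      cfg <- config
      cfg@kOn <- kon
      cfg@seed <- deriveSeed(seed, sprintf("sweep-%g-%d", kon, r))
      tr <- simulateTrace(cfg, duration)
      b <- tr$bursts
      if (nrow(b)) b <- b[which.max(b$duration), ]
      out <- rbind(out, data.frame(
        kon = kon, replicate = r,
        loadingRate = if (nrow(b)) b$loadingRate else NA_real_,
        burstDuration = if (nrow(b)) b$duration else NA_real_,
        maxEnrichment = max(tr$trace$rnapii),
        detectable = max(tr$trace$rnapii) >= detectionThreshold))
    }
  }
  out
}
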