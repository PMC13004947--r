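#' @import methods
#' @importFrom stats rnorm runif rbinom rgeom rexp sd quantile median approx
#'   wilcox.test dist optimize lm coef nls predict complete.cases setNames
#' @importFrom utils head tail read.csv write.csv modifyList
#' @importFrom graphics hist
#' @importFrom tools md5sum
#' @importFrom mclust Mclust mclustBIC
NULL

## ---------------------------------------------------------------------------
## Simulation configurations
## ---------------------------------------------------------------------------

#' Configuration for the single-molecule trajectory generator
#'
#' Holds all parameters of the Brownian-mixture trajectory simulator:
#' the number of trajectories, the mixing fractions and diffusion
#' coefficients of the kinetic states (bound, intermediate, fast, ...),
#' the frame interval, the per-localization noise, the geometric
#' track-length distribution and the circular nuclear geometry.
#'
#' @slot nTrajectories number of trajectories to simulate.
#' @slot stateFractions numeric vector of state weights, summing to 1.
#' @slot stateD diffusion coefficient per state, um^2/s, each in
#'   \[0.001, 100\].
#' @slot frameInterval frame interval in seconds.
#' @slot localizationSigma per-axis localization noise sd in um, added
#'   independently to every localization.
#' @slot meanTrackLength mean track length in frames (geometric
#'   truncation, minimum 3 localizations).
#' @slot nucleusRadius radius of the circular nuclear mask, um.
#' @slot nBoundHotspots number of circular hotspots in which bound-state
#'   trajectories are seeded (0 disables hotspot seeding).
#' @slot hotspotRadius hotspot radius, um.
#' @slot seed integer seed.
#' @seealso [smtSimConfig()], [simulateTrajectories()]
#' @exportClass SmtSimConfig
setClass("SmtSimConfig", representation(
  nTrajectories = "numeric", stateFractions = "numeric", stateD = "numeric",
  frameInterval = "numeric", localizationSigma = "numeric",
  meanTrackLength = "numeric", nucleusRadius = "numeric",
  nBoundHotspots = "numeric", hotspotRadius = "numeric", seed = "numeric"))

setValidity("SmtSimConfig", function(object) {
  msg <- character()
  if (object@nTrajectories < 1) msg <- c(msg, "nTrajectories must be >= 1")
  if (length(object@stateFractions) != length(object@stateD))
    msg <- c(msg, "stateFractions and stateD must have equal length")
  if (abs(sum(object@stateFractions) - 1) > 1e-9)
    msg <- c(msg, "stateFractions must sum to 1")
  if (any(object@stateFractions < 0)) msg <- c(msg, "stateFractions must be >= 0")
  if (any(object@stateD < 0.001 - 1e-12 & object@stateD != 0) ||
      any(object@stateD > 100))
    msg <- c(msg, "diffusion coefficients must lie in [0.001, 100] um^2/s (or be 0)")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@localizationSigma < 0) msg <- c(msg, "localizationSigma must be >= 0")
  if (object@nucleusRadius <= 0) msg <- c(msg, "nucleusRadius must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create an [SmtSimConfig-class] object
#'
#' Defaults emulate fast single-molecule tracking of RPB1 in a syncytial
#' embryo nucleus: a three-state mixture (chromatin bound, intermediate,
#' fast) with bound/intermediate/fast weights close to the nc13 values,
#' 10 ms frames and 30 nm localization noise.
#'
#' @param nTrajectories number of trajectories.
#' @param stateFractions state mixing weights (must sum to 1).
#' @param stateD per-state diffusion coefficients, um^2/s.
#' @param frameInterval frame interval, s.
#' @param localizationSigma per-axis localization noise sd, um.
#' @param meanTrackLength mean track length, frames.
#' @param nucleusRadius nuclear radius, um.
#' @param nBoundHotspots,hotspotRadius optional circular hotspots seeding
#'   bound trajectories.
#' @param seed integer seed.
#' @return an [SmtSimConfig-class] object.
#' @examples
#' cfg <- smtSimConfig(nTrajectories = 100, seed = 1)
#' @export
smtSimConfig <- function(nTrajectories = 1000,
                         stateFractions = c(0.37, 0.33, 0.30),
                         stateD = c(0.002, 0.2, 8),
                         frameInterval = 0.01,
                         localizationSigma = 0.030,
                         meanTrackLength = 8,
                         nucleusRadius = 2.5,
                         nBoundHotspots = 0,
                         hotspotRadius = 0.2,
                         seed = 1L) {
  new("SmtSimConfig", nTrajectories = nTrajectories,
      stateFractions = stateFractions, stateD = stateD,
      frameInterval = frameInterval, localizationSigma = localizationSigma,
      meanTrackLength = meanTrackLength, nucleusRadius = nucleusRadius,
      nBoundHotspots = nBoundHotspots, hotspotRadius = hotspotRadius,
      seed = seed)
}

#' Configuration for the volumetric nucleus-movie generator
#'
#' Describes a T x Z x Y x X movie of one nucleus: an ellipsoidal nuclear
#' baseline, transient Gaussian clusters whose lifetimes are drawn from a
#' two-population exponential mixture, up to two persistent bright
#' histone-locus bodies (HLBs), and additive Gaussian noise.
#'
#' @slot shape integer T, Z, Y, X extents in voxels.
#' @slot voxelSize um per voxel along z, y, x.
#' @slot nucleusCenter ellipsoid center, um (z, y, x).
#' @slot nucleusRadii ellipsoid radii, um (z, y, x).
#' @slot nClusters number of transient clusters.
#' @slot clusterAmplitude cluster peak height, fold over the nuclear
#'   baseline (must exceed 1).
#' @slot clusterSigma isotropic cluster sd, um.
#' @slot lifetimeMixture (weight_short, mean_short, mean_long) of the
#'   exponential lifetime mixture, minutes.
#' @slot frameInterval seconds between volumes.
#' @slot nHlbs number of HLBs, at most 2.
#' @slot hlbAmplitude HLB peak height, fold over baseline.
#' @slot hlbSigma HLB sd, um.
#' @slot baseline nuclear baseline intensity (a.u.).
#' @slot backgroundNoiseSigma additive Gaussian noise sd (a.u.).
#' @slot seed integer seed.
#' @exportClass NucleusMovieConfig
setClass("NucleusMovieConfig", representation(
  shape = "integer", voxelSize = "numeric", nucleusCenter = "numeric",
  nucleusRadii = "numeric", nClusters = "numeric", clusterAmplitude = "numeric",
  clusterSigma = "numeric", lifetimeMixture = "numeric",
  frameInterval = "numeric", nHlbs = "numeric", hlbAmplitude = "numeric",
  hlbSigma = "numeric", baseline = "numeric", backgroundNoiseSigma = "numeric",
  seed = "numeric"))

setValidity("NucleusMovieConfig", function(object) {
  msg <- character()
  if (length(object@shape) != 4 || any(object@shape < 1))
    msg <- c(msg, "shape must be positive T,Z,Y,X extents")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be positive (z,y,x) um")
  if (object@nHlbs > 2) msg <- c(msg, "at most 2 HLBs per nucleus")
  if (object@nClusters > 0 && object@clusterAmplitude <= 1)
    msg <- c(msg, "clusterAmplitude must be > 1")
  lm <- object@lifetimeMixture
  if (length(lm) != 3 || lm[1] < 0 || lm[1] > 1 || any(lm[2:3] <= 0))
    msg <- c(msg, "lifetimeMixture must be (weight_short in [0,1], mean_short > 0, mean_long > 0)")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a [NucleusMovieConfig-class] object
#'
#' Defaults emulate a deconvolved eGFP-RPB1 volume series: 0.108 um
#' lateral and 0.3 um axial voxels, 10 s between volumes, and a
#' short/long cluster-lifetime mixture matching a late-cycle nucleus.
#'
#' @param shape integer (T, Z, Y, X).
#' @param voxelSize um per voxel (z, y, x).
#' @param nucleusCenter,nucleusRadii ellipsoid, um (z, y, x); defaults
#'   center the nucleus in the volume.
#' @param nClusters,clusterAmplitude,clusterSigma transient clusters.
#' @param lifetimeMixture (weight_short, mean_short, mean_long), minutes.
#' @param frameInterval s per volume.
#' @param nHlbs,hlbAmplitude,hlbSigma persistent histone-locus bodies.
#' @param baseline nuclear baseline intensity.
#' @param backgroundNoiseSigma additive Gaussian noise sd.
#' @param seed integer seed.
#' @return a [NucleusMovieConfig-class] object.
#' @export
nucleusMovieConfig <- function(shape = c(40L, 16L, 64L, 64L),
                               voxelSize = c(0.3, 0.108, 0.108),
                               nucleusCenter = NULL,
                               nucleusRadii = NULL,
                               nClusters = 6,
                               clusterAmplitude = 3,
                               clusterSigma = 0.25,
                               lifetimeMixture = c(0.33, 2, 7),
                               frameInterval = 10,
                               nHlbs = 2,
                               hlbAmplitude = 8,
                               hlbSigma = 0.45,
                               baseline = 100,
                               backgroundNoiseSigma = 2,
                               seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(nucleusCenter))
    nucleusCenter <- shape[2:4] / 2 * voxelSize
  if (is.null(nucleusRadii))
    nucleusRadii <- shape[2:4] / 2 * voxelSize * 0.85
  new("NucleusMovieConfig", shape = shape, voxelSize = voxelSize,
      nucleusCenter = nucleusCenter, nucleusRadii = nucleusRadii,
      nClusters = nClusters, clusterAmplitude = clusterAmplitude,
      clusterSigma = clusterSigma, lifetimeMixture = lifetimeMixture,
      frameInterval = frameInterval, nHlbs = nHlbs,
      hlbAmplitude = hlbAmplitude, hlbSigma = hlbSigma, baseline = baseline,
      backgroundNoiseSigma = backgroundNoiseSigma, seed = seed)
}

#' Configuration of the stochastic polymerase-loading simulator
#'
#' All constants of the promoter-loading model: per-step loading and
#' dissociation probabilities, promoter ON duration, elongation rate and
#' gene length, nuclear and optical geometry, and sampling intervals.
#'
#' @slot kOn probability of loading one polymerase per time step while
#'   the promoter is ON.
#' @slot kOff probability per engaged polymerase per step of dissociating.
#' @slot tOn promoter ON duration, minutes.
#' @slot rElongation elongation rate, kb/min.
#' @slot geneLength gene length, kb.
#' @slot nucleusDiameter um.
#' @slot moleculeDiameter nm.
#' @slot geneRegionDiameter diameter of the analysis disc around the
#'   gene, um.
#' @slot psfFwhm point-spread-function full width at half maximum, nm.
#' @slot nTotalMolecules nucleus-wide RNAPII count.
#' @slot projectionSlices number of z slices in the max-projection slab.
#' @slot sliceThickness um per slice.
#' @slot dt simulation time step, s.
#' @slot subsampleInterval trace sampling interval, s.
#' @slot pixelSize um per pixel for rendering.
#' @slot seed integer seed.
#' @exportClass PolIISimConfig
setClass("PolIISimConfig", representation(
  kOn = "numeric", kOff = "numeric", tOn = "numeric", rElongation = "numeric",
  geneLength = "numeric", nucleusDiameter = "numeric",
  moleculeDiameter = "numeric", geneRegionDiameter = "numeric",
  psfFwhm = "numeric", nTotalMolecules = "numeric",
  projectionSlices = "numeric", sliceThickness = "numeric", dt = "numeric",
  subsampleInterval = "numeric", pixelSize = "numeric", seed = "numeric"))

setValidity("PolIISimConfig", function(object) {
  msg <- character()
  if (object@kOn < 0 || object@kOn > 1) msg <- c(msg, "kOn must be in [0,1]")
  if (object@kOff < 0 || object@kOff > 1) msg <- c(msg, "kOff must be in [0,1]")
  for (s in c("tOn", "rElongation", "geneLength", "nucleusDiameter",
              "moleculeDiameter", "geneRegionDiameter", "psfFwhm",
              "nTotalMolecules", "projectionSlices", "sliceThickness", "dt",
              "subsampleInterval", "pixelSize"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (length(msg)) msg else TRUE
})

#' Create a [PolIISimConfig-class] object
#'
#' Defaults are the published constants of the burst-visibility model:
#' promoter ON time 15 min, elongation 2.5 kb/min, gene 2.8 kb, nucleus
#' 5 um, molecule 15 nm, gene-region disc 1 um, PSF FWHM 400 nm, 50,000
#' nuclear molecules, 0.1 s steps subsampled every 9 s at 0.108 um
#' pixels.
#'
#' @param kOn,kOff per-step loading/dissociation probabilities.
#' @param tOn promoter ON duration, min.
#' @param rElongation elongation rate, kb/min.
#' @param geneLength kb.
#' @param nucleusDiameter um.
#' @param moleculeDiameter nm.
#' @param geneRegionDiameter um.
#' @param psfFwhm nm.
#' @param nTotalMolecules nucleus-wide molecule count.
#' @param projectionSlices,sliceThickness projection slab geometry.
#' @param dt time step, s.
#' @param subsampleInterval s.
#' @param pixelSize um.
#' @param seed integer seed.
#' @return a [PolIISimConfig-class] object.
#' @export
polIISimConfig <- function(kOn = 0.2, kOff = 0.001, tOn = 15,
                           rElongation = 2.5, geneLength = 2.8,
                           nucleusDiameter = 5, moleculeDiameter = 15,
                           geneRegionDiameter = 1, psfFwhm = 400,
                           nTotalMolecules = 50000, projectionSlices = 3,
                           sliceThickness = 0.3, dt = 0.1,
                           subsampleInterval = 9, pixelSize = 0.108,
                           seed = 1L) {
  new("PolIISimConfig", kOn = kOn, kOff = kOff, tOn = tOn,
      rElongation = rElongation, geneLength = geneLength,
      nucleusDiameter = nucleusDiameter, moleculeDiameter = moleculeDiameter,
      geneRegionDiameter = geneRegionDiameter, psfFwhm = psfFwhm,
      nTotalMolecules = nTotalMolecules, projectionSlices = projectionSlices,
      sliceThickness = sliceThickness, dt = dt,
      subsampleInterval = subsampleInterval, pixelSize = pixelSize,
      seed = seed)
}

## ---------------------------------------------------------------------------
## Analysis results
## ---------------------------------------------------------------------------

#' Diffusion-coefficient occupancy profile
#'
#' Posterior mass over a fixed log-spaced grid of diffusion coefficients,
#' estimated from a set of trajectories, together with the per-trajectory
#' posterior responsibilities used for state assignment.
#'
#' @slot grid diffusion coefficients, um^2/s (log-spaced, 0.001-100).
#' @slot occupancy nonnegative weights summing to 1.
#' @slot localizationSigma localization noise used in the likelihood, um.
#' @slot nTrajectories number of trajectories fit.
#' @slot responsibilities nTrajectories x length(grid) posterior matrix.
#' @slot logLik log-likelihood trace across EM iterations.
#' @exportClass OccupancyProfile
setClass("OccupancyProfile", representation(
  grid = "numeric", occupancy = "numeric", localizationSigma = "numeric",
  nTrajectories = "numeric", responsibilities = "matrix", logLik = "numeric"))

setValidity("OccupancyProfile", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@occupancy))
    msg <- c(msg, "grid and occupancy lengths differ")
  if (any(object@occupancy < -1e-12)) msg <- c(msg, "occupancy must be >= 0")
  if (abs(sum(object@occupancy) - 1) > 1e-9)
    msg <- c(msg, "occupancy must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Kinetic-state bins over the diffusion-coefficient axis
#'
#' Cut points dividing the diffusion-coefficient axis into ordered
#' kinetic states. The first bin starts at the low end of the grid and
#' the last ends at its high end.
#'
#' @slot boundaries strictly increasing cut points, um^2/s.
#' @slot labels state names, one more than boundaries.
#' @slot gridRange the (min, max) of the grid the bins refer to.
#' @exportClass KineticBins
setClass("KineticBins", representation(
  boundaries = "numeric", labels = "character", gridRange = "numeric"))

setValidity("KineticBins", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@boundaries) + 1)
    msg <- c(msg, "need exactly one more label than boundaries")
  if (length(object@boundaries) && any(diff(object@boundaries) <= 0))
    msg <- c(msg, "boundaries must be strictly increasing")
  if (length(object@boundaries) &&
      (min(object@boundaries) <= object@gridRange[1] ||
       max(object@boundaries) >= object@gridRange[2]))
    msg <- c(msg, "boundaries must lie strictly inside the grid range")
  if (length(msg)) msg else TRUE
})

#' Two-population cluster-lifetime mixture fit
#'
#' Maximum-likelihood two-component univariate Gaussian mixture fit of
#' cluster lifetimes, components ordered by mean. The weight uncertainty
#' is the binomial standard deviation sqrt(w (1 - w) / n) using the
#' number of clusters fit.
#'
#' @slot weights mixing weights (short, long), summing to 1.
#' @slot means component means, minutes (mean_short < mean_long).
#' @slot sds component standard deviations, minutes.
#' @slot weightSd binomial uncertainty of each weight.
#' @slot nClusters number of lifetimes fit.
#' @slot logLik fit log-likelihood.
#' @exportClass LifetimeMixture
setClass("LifetimeMixture", representation(
  weights = "numeric", means = "numeric", sds = "numeric",
  weightSd = "numeric", nClusters = "numeric", logLik = "numeric"))

setValidity("LifetimeMixture", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (length(object@means) == 2 && object@means[1] >= object@means[2])
    msg <- c(msg, "components must be ordered by mean")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @describeIn OccupancyProfile-class occupancy weights.
#' @param object an object.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @export
setMethod("occupancy", "OccupancyProfile", function(object) object@occupancy)

#' @describeIn OccupancyProfile-class the diffusion-coefficient grid.
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @export
setMethod("gridValues", "OccupancyProfile", function(object) object@grid)

#' @describeIn KineticBins-class bin cut points, um^2/s.
#' @export
setGeneric("binBoundaries", function(object) standardGeneric("binBoundaries"))
#' @export
setMethod("binBoundaries", "KineticBins", function(object) object@boundaries)

#' @describeIn KineticBins-class ordered state labels.
#' @export
setGeneric("binLabels", function(object) standardGeneric("binLabels"))
#' @export
setMethod("binLabels", "KineticBins", function(object) object@labels)

#' @describeIn LifetimeMixture-class mixing weights (short, long).
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @export
setMethod("mixtureWeights", "LifetimeMixture", function(object) object@weights)

#' @describeIn LifetimeMixture-class component means, minutes.
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))
#' @export
setMethod("mixtureMeans", "LifetimeMixture", function(object) object@means)

setMethod("show", "OccupancyProfile", function(object) {
  cat("OccupancyProfile over", length(object@grid),
      "diffusion coefficients in [",
      format(min(object@grid)), ",", format(max(object@grid)), "] um^2/s\n")
  cat("  fit to", object@nTrajectories, "trajectories; sigma_loc =",
      object@localizationSigma, "um\n")
  mode <- object@grid[which.max(object@occupancy)]
  cat("  modal D =", signif(mode, 3), "um^2/s\n")
})

setMethod("show", "KineticBins", function(object) {
  cat("KineticBins:", length(object@labels), "states\n")
  lo <- c(object@gridRange[1], object@boundaries)
  hi <- c(object@boundaries, object@gridRange[2])
  for (i in seq_along(object@labels))
    cat(sprintf("  %-12s [%g, %g] um^2/s\n", object@labels[i], lo[i], hi[i]))
})

setMethod("show", "LifetimeMixture", function(object) {
  cat("LifetimeMixture (2-state GMM of", object@nClusters, "lifetimes)\n")
  cat(sprintf("  short-lived: weight %.2f +- %.2f, mean %.2f min\n",
              object@weights[1], object@weightSd[1], object@means[1]))
  cat(sprintf("  long-lived:  weight %.2f +- %.2f, mean %.2f min\n",
              object@weights[2], object@weightSd[2], object@means[2]))
})

setMethod("show", "SmtSimConfig", function(object) {
  cat("SmtSimConfig:", object@nTrajectories, "trajectories,",
      length(object@stateD), "states\n")
  cat("  D =", paste(object@stateD, collapse = "/"), "um^2/s, fractions",
      paste(object@stateFractions, collapse = "/"), "\n")
  cat("  dt =", object@frameInterval, "s, sigma_loc =",
      object@localizationSigma, "um, nucleus R =", object@nucleusRadius, "um\n")
})

setMethod("show", "PolIISimConfig", function(object) {
  cat("PolIISimConfig: k_on =", object@kOn, ", k_off =", object@kOff,
      "per", object@dt, "s step\n")
  cat("  t_on =", object@tOn, "min, gene", object@geneLength, "kb at",
      object@rElongation, "kb/min\n")
})
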