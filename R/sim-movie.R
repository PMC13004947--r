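## Synthetic volumetric nucleus movies: ellipsoidal baseline, transient
## Gaussian clusters with two-population exponential lifetimes, up to two
## persistent HLBs, and additive Gaussian noise (emulating deconvolved
## data, where shot statistics are already distorted).

## add an isotropic Gaussian blob (sigma in um) to a Z x Y x X volume
addBlob <- function(vol, center, sigma, amplitude, voxelSize) {
  d <- dim(vol)
  sv <- sigma / voxelSize                      # sigma per axis, voxels
  ctr <- center / voxelSize + 0.5              # voxel-center coordinates
  g <- lapply(1:3, function(ax) {
    lo <- max(1, floor(ctr[ax] - 4 * sv[ax]))
    hi <- min(d[ax], ceiling(ctr[ax] + 4 * sv[ax]))
    if (lo > hi) return(NULL)
    i <- lo:hi
    list(idx = i, w = exp(-((i - ctr[ax]) * voxelSize[ax])^2 /
                            (2 * sigma^2)))
  })
  if (any(vapply(g, is.null, logical(1)))) return(vol)
  blob <- amplitude * (g[[1]]$w %o% g[[2]]$w %o% g[[3]]$w)
  vol[g[[1]]$idx, g[[2]]$idx, g[[3]]$idx] <-
    vol[g[[1]]$idx, g[[2]]$idx, g[[3]]$idx] + blob
  vol
}

## uniform point inside an ellipsoid, shrunk by `margin` (fraction)
ellipsoidPoint <- function(center, radii, margin = 0.25) {
  repeat {
    u <- runif(3, -1, 1)
    if (sum(u^2) <= 1) return(center + u * radii * (1 - margin))
  }
}

#' Simulate a volumetric nucleus movie with transient clusters
#'
#' Builds a T x Z x Y x X stack: a constant baseline inside the nuclear
#' ellipsoid, isotropic Gaussian blobs for transient clusters (lifetimes
#' drawn from the two-population exponential mixture, birth frames
#' uniform over the movie) and for up to two bright HLBs that persist
#' the whole movie, plus additive Gaussian noise.
#'
#' @param config a [NucleusMovieConfig-class] object.
#' @return a list with
#'   \describe{
#'     \item{movie}{4D array (T, Z, Y, X).}
#'     \item{mask}{logical nuclear mask (Z, Y, X).}
#'     \item{truth}{data.frame of ground-truth blobs: `id`, `z`, `y`,
#'       `x` (um), `birthFrame`, `deathFrame`, `nFrames`, `lifetimeMin`,
#'       `amplitude` (a.u. peak above baseline), `sigma`, `isHlb`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulateNucleusMovie <- function(config) {
  stopifnot(is(config, "NucleusMovieConfig"))
  validObject(config)
  set.seed(config@seed)
  d <- config@shape
  vs <- config@voxelSize
  ## nuclear mask from voxel centers
  zc <- (seq_len(d[2]) - 0.5) * vs[1]
  yc <- (seq_len(d[3]) - 0.5) * vs[2]
  xc <- (seq_len(d[4]) - 0.5) * vs[3]
  fz <- ((zc - config@nucleusCenter[1]) / config@nucleusRadii[1])^2
  fy <- ((yc - config@nucleusCenter[2]) / config@nucleusRadii[2])^2
  fx <- ((xc - config@nucleusCenter[3]) / config@nucleusRadii[3])^2
  mask <- outer(outer(fz, fy, `+`), fx, `+`) <= 1

  nT <- d[1]
  truth <- NULL
  mkRow <- function(id, pos, birth, death, amp, sigma, isHlb) {
    data.frame(id = id, z = pos[1], y = pos[2], x = pos[3],
               birthFrame = birth, deathFrame = death,
               nFrames = death - birth + 1L,
               lifetimeMin = (death - birth + 1L) * config@frameInterval / 60,
               amplitude = amp, sigma = sigma, isHlb = isHlb)
  }
  id <- 0L
  if (config@nClusters > 0) {
    life <- sampleLifetimes(config@nClusters, config@lifetimeMixture)
    nFr <- pmax(1L, round(life * 60 / config@frameInterval))
    for (i in seq_len(config@nClusters)) {
      id <- id + 1L
      birth <- sample.int(nT, 1)
      death <- min(nT, birth + nFr[i] - 1L)
      pos <- ellipsoidPoint(config@nucleusCenter, config@nucleusRadii)
      truth <- rbind(truth, mkRow(id, pos, birth, death,
                                  (config@clusterAmplitude - 1) * config@baseline,
                                  config@clusterSigma, FALSE))
    }
  }
  if (config@nHlbs > 0) {
    for (i in seq_len(config@nHlbs)) {
      id <- id + 1L
      pos <- ellipsoidPoint(config@nucleusCenter, config@nucleusRadii)
      truth <- rbind(truth, mkRow(id, pos, 1L, nT,
                                  (config@hlbAmplitude - 1) * config@baseline,
                                  config@hlbSigma, TRUE))
    }
  }

  base <- array(0, d[2:4])
  base[mask] <- config@baseline
  movie <- array(0, d)
  for (t in seq_len(nT)) {
    vol <- base
    if (!is.null(truth)) {
      act <- which(truth$birthFrame <= t & truth$deathFrame >= t)
      for (i in act)
        vol <- addBlob(vol, c(truth$z[i], truth$y[i], truth$x[i]),
                       truth$sigma[i], truth$amplitude[i], vs)
    }
    movie[t, , , ] <- vol
  }
  if (config@backgroundNoiseSigma > 0)
    movie <- movie + rnorm(length(movie)) * config@backgroundNoiseSigma
  if (is.null(truth))
    truth <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                        x = numeric(0), birthFrame = integer(0),
                        deathFrame = integer(0), nFrames = integer(0),
                        lifetimeMin = numeric(0), amplitude = numeric(0),
                        sigma = numeric(0), isHlb = logical(0))
  list(movie = movie, mask = mask, truth = truth, config = config)
}
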