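## Volumetric cluster analysis: nuclear normalization, segmentation,
## HLB detection, enrichment filtering, density, lifetime tracking and
## the two-population lifetime mixture.

#' Normalize a nuclear volume to its mean intensity
#'
#' Every voxel inside the nuclear mask is divided by the mean intensity
#' inside the mask, yielding local enrichment over nuclear background;
#' voxels outside the mask are set to 0. The mean of the output inside
#' the mask is exactly 1.
#'
#' @param volume 3D array (Z, Y, X).
#' @param mask logical 3D array, same shape.
#' @return enrichment volume, same shape.
#' @export
normalizeNucleus <- function(volume, mask) {
  stopifnot(identical(dim(volume), dim(mask)))
  if (!any(mask)) stop("empty nuclear mask")
  mu <- mean(volume[mask])
  if (mu == 0) stop("zero mean intensity inside mask")
  out <- volume / mu
  out[!mask] <- 0
  out
}

#' Segment intra-nuclear clusters in an enrichment volume
#'
#' Operator chain: per-slice median filter, grayscale erosion,
#' reconstruction by dilation, subtraction of the reconstruction from
#' the median-filtered image (a top-hat that removes the smooth nuclear
#' background), Otsu binarization of the residue, local-maxima markers
#' and a seeded watershed to split touching clusters, followed by
#' region properties per label.
#'
#' @param enrichment normalized volume from [normalizeNucleus()].
#' @param mask logical nuclear mask; defaults to `enrichment > 0`.
#' @param voxelSize um per voxel (z, y, x).
#' @param medianRadius per-slice median filter radius, voxels.
#' @param erosionRadius erosion ball radius, voxels.
#' @param minSeparation minimal marker separation, voxels.
#' @param minVoxels discard segmented objects smaller than this.
#' @param threshold binarization threshold for the top-hat residue;
#'   `"otsu"` (default) or a number.
#' @return list with `clusters` (data.frame: `cluster`, `z`, `y`, `x`
#'   centroid in um, `nVoxels`, `volumeUm3`, `meanEnrichment`,
#'   `integratedIntensity`, `maxEnrichment`) and `labels` (integer
#'   volume).
#' @export
segmentClusters <- function(enrichment, mask = NULL,
                            voxelSize = c(0.3, 0.108, 0.108),
                            medianRadius = 1, erosionRadius = 2,
                            minSeparation = 3, minVoxels = 3,
                            threshold = "otsu") {
  if (is.null(mask)) mask <- enrichment > 0
  empty <- list(clusters = emptySegTable(), labels = array(0L, dim(enrichment)))
  med <- medianFilterSlices(enrichment, medianRadius)
  ero <- greyErode3(med, erosionRadius)
  rec <- reconstructByDilation(ero, med)
  tophat <- pmax(med - rec, 0)
  tophat[!mask] <- 0
  v <- tophat[mask]
  if (max(v) <= 0) return(empty)
  th <- if (identical(threshold, "otsu")) otsuThreshold(v[v > 0]) else threshold
  binary <- tophat > th & mask
  if (!any(binary)) return(empty)
  ## drop specks
  cc <- EBImage::bwlabel(binary)
  sizes <- tabulate(cc[cc > 0])
  speck <- which(cc > 0)
  speck <- speck[sizes[cc[speck]] < minVoxels]
  binary[speck] <- FALSE
  if (!any(binary)) return(empty)
  markers <- localMaxima3(tophat, binary, minSeparation)
  labels <- seededWatershed(tophat, binary, markers)
  ## compact label ids
  ids <- sort(unique(labels[labels > 0]))
  labels <- array(match(labels, c(0L, ids)) - 1L, dim(labels))
  clusters <- do.call(rbind, lapply(seq_along(ids), function(k) {
    w <- which(labels == k)
    co <- arrayInd(w, dim(labels))
    data.frame(cluster = k,
               z = mean((co[, 1] - 0.5) * voxelSize[1]),
               y = mean((co[, 2] - 0.5) * voxelSize[2]),
               x = mean((co[, 3] - 0.5) * voxelSize[3]),
               nVoxels = length(w),
               volumeUm3 = length(w) * prod(voxelSize),
               meanEnrichment = mean(enrichment[w]),
               integratedIntensity = sum(enrichment[w]),
               maxEnrichment = max(enrichment[w]))
  }))
  list(clusters = clusters, labels = labels)
}

emptySegTable <- function() {
  data.frame(cluster = integer(0), z = numeric(0), y = numeric(0),
             x = numeric(0), nVoxels = integer(0), volumeUm3 = numeric(0),
             meanEnrichment = numeric(0), integratedIntensity = numeric(0),
             maxEnrichment = numeric(0))
}

#' Detect histone-locus bodies and remove them from the cluster list
#'
#' A per-slice difference of Gaussians (sigma low then sigma high, in
#' pixel units) is thresholded at a high percentile; among segmented
#' clusters overlapping the response, the (up to) two with the highest
#' mean enrichment are flagged as HLBs, reflecting that a nucleus holds
#' at most two.
#'
#' @param enrichment normalized volume.
#' @param seg output of [segmentClusters()].
#' @param sigmaLow,sigmaHigh DoG sigmas in pixels (defaults 1 and 5).
#' @param percentile DoG threshold percentile (default 0.9995).
#' @param mask logical mask; defaults to `enrichment > 0`.
#' @return list with `hlbs` and `clusters` data.frames (the latter with
#'   HLBs removed).
#' @export
detectHlbs <- function(enrichment, seg, sigmaLow = 1, sigmaHigh = 5,
                       percentile = 0.9995, mask = NULL) {
  if (is.null(mask)) mask <- enrichment > 0
  dog <- enrichment
  for (z in seq_len(dim(enrichment)[1]))
    dog[z, , ] <- EBImage::gblur(enrichment[z, , ], sigma = sigmaLow) -
      EBImage::gblur(enrichment[z, , ], sigma = sigmaHigh)
  thr <- quantile(dog[mask], percentile)
  dogMask <- dog >= thr & mask
  overlapping <- unique(seg$labels[dogMask & seg$labels > 0])
  cand <- seg$clusters[seg$clusters$cluster %in% overlapping, , drop = FALSE]
  cand <- cand[order(cand$meanEnrichment, decreasing = TRUE), , drop = FALSE]
  hlbIds <- head(cand$cluster, 2)
  list(hlbs = seg$clusters[seg$clusters$cluster %in% hlbIds, , drop = FALSE],
       clusters = seg$clusters[!seg$clusters$cluster %in% hlbIds, ,
                               drop = FALSE])
}

#' Filter clusters by mean enrichment
#'
#' Retains clusters whose mean enrichment over the nuclear background is
#' at least `threshold`; the default of 1.65 separates genuine clusters
#' from background fluctuations.
#'
#' @param clusters cluster table.
#' @param threshold minimal mean enrichment (default 1.65).
#' @return filtered table.
#' @export
filterByEnrichment <- function(clusters, threshold = 1.65) {
  clusters[clusters$meanEnrichment >= threshold, , drop = FALSE]
}

#' Cluster density
#'
#' @param clusters cluster table or a count.
#' @param nuclearVolume nuclear volume, um^3.
#' @return clusters per um^3.
#' @export
clusterDensity <- function(clusters, nuclearVolume) {
  if (nuclearVolume <= 0) stop("nuclear volume must be > 0")
  n <- if (is.data.frame(clusters)) nrow(clusters) else clusters
  n / nuclearVolume
}

#' Track cluster lifetimes across frames
#'
#' Frame-to-frame nearest-neighbor linking of segmented clusters. A link
#' requires an axial displacement of at most `zTolerance` (600 nm, i.e.
#' two 300 nm z-slices, by default) and a lateral displacement of at
#' most `xyLinkRadius`; a track ends at the first frame without a link.
#' Lifetime is the number of linked frames times the frame interval;
#' the normalized lifetime divides by the movie duration.
#'
#' @param detections data.frame with columns `frame`, `z`, `y`, `x`
#'   (um), e.g. per-frame [segmentClusters()] centroids.
#' @param frameInterval seconds between frames.
#' @param nTotalFrames total movie length, frames.
#' @param zTolerance maximal |dz| per link, um (default 0.6).
#' @param xyLinkRadius maximal lateral distance per link, um.
#' @return data.frame per track: `track`, `startFrame`, `endFrame`,
#'   `nFrames`, `lifetimeMin`, `normalizedLifetime`.
#' @export
trackLifetimes <- function(detections, frameInterval, nTotalFrames,
                           zTolerance = 0.6, xyLinkRadius = 0.5) {
  if (nrow(detections) == 0)
    return(data.frame(track = integer(0), startFrame = integer(0),
                      endFrame = integer(0), nFrames = integer(0),
                      lifetimeMin = numeric(0),
                      normalizedLifetime = numeric(0)))
  frames <- sort(unique(detections$frame))
  detections$track <- NA_integer_
  nextTrack <- 1L
  prevIdx <- integer(0)
  for (fi in seq_along(frames)) {
    cur <- which(detections$frame == frames[fi])
    newIdx <- cur
    if (length(prevIdx) && fi > 1 && frames[fi] == frames[fi - 1] + 1) {
      ## greedy linking by increasing lateral distance
      pairs <- expand.grid(p = prevIdx, c = cur)
      dz <- abs(detections$z[pairs$p] - detections$z[pairs$c])
      dxy <- sqrt((detections$y[pairs$p] - detections$y[pairs$c])^2 +
                  (detections$x[pairs$p] - detections$x[pairs$c])^2)
      ok <- dz <= zTolerance & dxy <= xyLinkRadius
      pairs <- pairs[ok, , drop = FALSE]; dxy <- dxy[ok]
      usedP <- usedC <- integer(0)
      for (k in order(dxy)) {
        p <- pairs$p[k]; cc <- pairs$c[k]
        if (p %in% usedP || cc %in% usedC) next
        detections$track[cc] <- detections$track[p]
        usedP <- c(usedP, p); usedC <- c(usedC, cc)
      }
      newIdx <- setdiff(cur, usedC)
    }
    for (i in newIdx) {
      detections$track[i] <- nextTrack
      nextTrack <- nextTrack + 1L
    }
    prevIdx <- cur
  }
  agg <- split(detections$frame, detections$track)
  out <- do.call(rbind, lapply(names(agg), function(tr) {
    f <- agg[[tr]]
    data.frame(track = as.integer(tr), startFrame = min(f),
               endFrame = max(f), nFrames = length(f))
  }))
  out <- out[order(out$track), ]
  out$lifetimeMin <- out$nFrames * frameInterval / 60
  out$normalizedLifetime <- out$nFrames / nTotalFrames
  rownames(out) <- NULL
  out
}

#' Fit a two-population Gaussian mixture to cluster lifetimes
#'
#' Maximum-likelihood univariate Gaussian mixture on raw lifetimes in
#' minutes (unequal variances), components ordered by mean. The weight
#' uncertainty is the binomial standard deviation `sqrt(w (1 - w) / n)`
#' with `n` the number of clusters fit.
#'
#' @param lifetimes lifetimes in minutes (at least 20).
#' @param nComponents number of components (default 2).
#' @param seed kept for interface stability; the fit itself is
#'   deterministic (hierarchical-clustering initialization).
#' @return a [LifetimeMixture-class] object.
#' @export
fitLifetimeMixture <- function(lifetimes, nComponents = 2, seed = 1L) {
  if (length(lifetimes) < 20) stop("need at least 20 lifetimes")
  fit <- tryCatch(
    Mclust(lifetimes, G = nComponents, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- Mclust(lifetimes, G = nComponents, modelNames = "E",
                  verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  p <- fit$parameters
  mu <- as.numeric(p$mean)
  w <- as.numeric(p$pro)
  sig <- sqrt(as.numeric(p$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  o <- order(mu)
  w <- w[o]; mu <- mu[o]; sig <- sig[o]
  n <- length(lifetimes)
  new("LifetimeMixture", weights = w, means = mu, sds = sig,
      weightSd = sqrt(w * (1 - w) / n), nClusters = n,
      logLik = as.numeric(fit$loglik))
}

#' Sample cluster lifetimes from a two-population mixture
#'
#' With probability `mixture[1]` a lifetime belongs to the short-lived
#' population (mean `mixture[2]` minutes), otherwise to the long-lived
#' one (mean `mixture[3]`). The `"exponential"` family (memoryless
#' dissolution, used by the movie generator) draws exponential
#' lifetimes; the `"gaussian"` family draws normal lifetimes with the
#' given component sds, truncated at a small positive floor -- this is
#' the generating model under which the two-component Gaussian mixture
#' fit of [fitLifetimeMixture()] is well specified and recoverable.
#'
#' @param n number of lifetimes.
#' @param mixture `(weight_short, mean_short, mean_long)`, minutes.
#' @param seed optional integer seed.
#' @param family `"exponential"` or `"gaussian"`.
#' @param sds component sds for the Gaussian family, minutes.
#' @return lifetimes in minutes.
#' @export
sampleLifetimes <- function(n, mixture = c(0.33, 2, 7), seed = NULL,
                            family = c("exponential", "gaussian"),
                            sds = c(0.8, 2)) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  short <- runif(n) < mixture[1]
  if (family == "exponential")
    return(ifelse(short, rexp(n, 1 / mixture[2]), rexp(n, 1 / mixture[3])))
  mu <- ifelse(short, mixture[2], mixture[3])
  sg <- ifelse(short, sds[1], sds[2])
  pmax(rnorm(n, mu, sg), 0.05)
}

#' Segment every frame of a nucleus movie
#'
#' Convenience wrapper applying [normalizeNucleus()] and
#' [segmentClusters()] per time point, returning a detections table
#' ready for [trackLifetimes()].
#'
#' @param movie 4D array (T, Z, Y, X).
#' @param mask logical (Z, Y, X) nuclear mask.
#' @param voxelSize um per voxel (z, y, x).
#' @param enrichmentThreshold minimal mean enrichment, applied per frame
#'   via [filterByEnrichment()]; `NULL` disables.
#' @param ... passed to [segmentClusters()].
#' @return data.frame of per-frame cluster centroids with a `frame`
#'   column.
#' @export
segmentMovieClusters <- function(movie, mask,
                                 voxelSize = c(0.3, 0.108, 0.108),
                                 enrichmentThreshold = NULL, ...) {
  out <- lapply(seq_len(dim(movie)[1]), function(t) {
    enr <- normalizeNucleus(movie[t, , , ], mask)
    cl <- segmentClusters(enr, mask, voxelSize = voxelSize, ...)$clusters
    if (!is.null(enrichmentThreshold))
      cl <- filterByEnrichment(cl, enrichmentThreshold)
    if (nrow(cl)) cbind(frame = t, cl) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(frame = integer(0), emptySegTable())
  out
}

#' Subsample cluster lifetimes by nucleus
#'
#' Mirrors the manual sampling protocol: at most `maxPerNucleus`
#' clusters are drawn (without replacement, seeded) from each nucleus,
#' and nuclei groups below `minNuclei` trigger a warning since the
#' protocol requires several nuclei per embryo.
#'
#' @param tracks track table (e.g. [trackLifetimes()] output) with an
#'   added `nucleus` column.
#' @param maxPerNucleus maximal clusters per nucleus (default 8).
#' @param minNuclei minimal number of nuclei expected (default 5).
#' @param seed integer seed.
#' @return subsampled track table.
#' @export
subsampleLifetimes <- function(tracks, maxPerNucleus = 8, minNuclei = 5,
                               seed = 1L) {
  stopifnot("nucleus" %in% names(tracks))
  set.seed(seed)
  if (length(unique(tracks$nucleus)) < minNuclei)
    warning("fewer than ", minNuclei, " nuclei in input")
  keep <- unlist(lapply(split(seq_len(nrow(tracks)), tracks$nucleus),
                        function(i) {
    if (length(i) <= maxPerNucleus) i
    else sample(i, maxPerNucleus)
  }))
  tracks[sort(keep), , drop = FALSE]
}
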