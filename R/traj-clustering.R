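## Density-based clustering of trajectory mean positions, matched
## control spots, and inside/outside kinetics.

#' Mean position of each trajectory
#'
#' @param tracks trajectory table.
#' @return data.frame with columns `trajectory`, `x`, `y` (um).
#' @export
meanPositions <- function(tracks) {
  if (is.null(tracks) || nrow(tracks) == 0) stop("no trajectories")
  agg <- rowsum(cbind(tracks$x, tracks$y, 1), tracks$trajectory)
  data.frame(trajectory = rownames(agg), x = agg[, 1] / agg[, 3],
             y = agg[, 2] / agg[, 3], row.names = NULL)
}

#' Density-based clustering of points
#'
#' Standard density-based clustering: a core point has at least
#' `minSamples` points (itself included) within `eps`; clusters are the
#' connected components of core points, plus border points reachable
#' from them. Border points reachable from two clusters are assigned to
#' the cluster expanded first in point order, which makes the result
#' deterministic under a fixed point order.
#'
#' @param points data.frame with columns `x`, `y` (um), one nucleus.
#' @param eps neighborhood radius, um (default 0.2).
#' @param minSamples minimal neighborhood size of a core point
#'   (default 15).
#' @return list with
#'   \describe{
#'     \item{labels}{integer vector, 0 for noise, 1..k for clusters.}
#'     \item{clusters}{data.frame per cluster: `cluster`, `x`, `y`
#'       (centroid), `radius` (max member distance to centroid), `n`.}
#'   }
#' @export
densityCluster <- function(points, eps = 0.2, minSamples = 15) {
  n <- nrow(points)
  labels <- integer(n)
  if (n == 0) return(list(labels = labels, clusters = emptyClusterTable()))
  d <- as.matrix(dist(cbind(points$x, points$y)))
  nb <- d <= eps
  core <- rowSums(nb) >= minSamples
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      reach <- which(nb[frontier[1], ])
      frontier <- frontier[-1]
      for (j in reach) {
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) frontier <- c(frontier, j)
        }
      }
    }
  }
  list(labels = labels, clusters = clusterTable(points, labels))
}

emptyClusterTable <- function() {
  data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
             radius = numeric(0), n = integer(0))
}

clusterTable <- function(points, labels) {
  ks <- sort(unique(labels[labels > 0]))
  if (!length(ks)) return(emptyClusterTable())
  do.call(rbind, lapply(ks, function(k) {
    px <- points$x[labels == k]; py <- points$y[labels == k]
    cx <- mean(px); cy <- mean(py)
    data.frame(cluster = k, x = cx, y = cy,
               radius = max(sqrt((px - cx)^2 + (py - cy)^2)),
               n = length(px))
  }))
}

#' Cluster count as a function of the neighborhood radius
#'
#' Scan used to pick `eps` by the elbow criterion; no automatic knee
#' selection is performed.
#'
#' @param points data.frame with `x`, `y`.
#' @param epsValues increasing radii to scan, um.
#' @param minSamples as in [densityCluster()].
#' @return data.frame with columns `eps` and `nClusters`.
#' @export
epsElbowScan <- function(points, epsValues, minSamples = 15) {
  stopifnot(all(diff(epsValues) > 0))
  data.frame(eps = epsValues,
             nClusters = vapply(epsValues, function(e)
               nrow(densityCluster(points, e, minSamples)$clusters),
               numeric(1)))
}

#' Drop likely histone-locus bodies from a cluster table
#'
#' Clusters that are extreme in both member count and radius (above the
#' given quantile of each, within the nucleus) are removed; these are
#' likely HLBs or random accumulations rather than typical clusters.
#'
#' @param clusters cluster table from [densityCluster()].
#' @param quantileCut quantile above which both size measures must fall
#'   (default 0.95).
#' @return filtered cluster table.
#' @export
filterTrajClusters <- function(clusters, quantileCut = 0.95) {
  if (nrow(clusters) < 2) return(clusters)
  big <- clusters$n > quantile(clusters$n, quantileCut) &
    clusters$radius > quantile(clusters$radius, quantileCut)
  clusters[!big, , drop = FALSE]
}

#' Place size-matched control spots
#'
#' For each cluster, `nPerCluster` control spots of the same effective
#' radius are rejection-sampled inside the circular nuclear mask such
#' that they overlap neither any cluster nor any other control spot.
#'
#' @param clusters cluster table from [densityCluster()].
#' @param nucleusCenter circle center (x, y), um.
#' @param nucleusRadius circle radius, um.
#' @param nPerCluster spots per cluster (default 30).
#' @param seed integer seed.
#' @param maxAttempts rejection-sampling budget per spot.
#' @return data.frame of spots (`spot`, `cluster`, `x`, `y`, `radius`);
#'   a warning is raised if placement fails and the list is partial.
#' @export
placeControlSpots <- function(clusters, nucleusCenter = c(0, 0),
                              nucleusRadius = 2.5, nPerCluster = 30,
                              seed = 1L, maxAttempts = 2000) {
  set.seed(seed)
  spots <- data.frame(spot = integer(0), cluster = integer(0),
                      x = numeric(0), y = numeric(0), radius = numeric(0))
  if (nrow(clusters) == 0) return(spots)
  sp <- 0L
  for (ci in seq_len(nrow(clusters))) {
    r <- clusters$radius[ci]
    placed <- 0L
    attempts <- 0L
    while (placed < nPerCluster && attempts < maxAttempts) {
      attempts <- attempts + 1L
      u <- runif(1); a <- runif(1)
      rad <- max(nucleusRadius - r, 0) * sqrt(u)
      x <- nucleusCenter[1] + rad * cos(2 * pi * a)
      y <- nucleusCenter[2] + rad * sin(2 * pi * a)
      dc <- sqrt((clusters$x - x)^2 + (clusters$y - y)^2)
      if (any(dc < clusters$radius + r)) next
      if (nrow(spots)) {
        ds <- sqrt((spots$x - x)^2 + (spots$y - y)^2)
        if (any(ds < spots$radius + r)) next
      }
      sp <- sp + 1L; placed <- placed + 1L
      spots[nrow(spots) + 1L, ] <- list(sp, clusters$cluster[ci], x, y, r)
    }
    if (placed < nPerCluster)
      warning(sprintf("cluster %d: placed %d of %d control spots",
                      clusters$cluster[ci], placed, nPerCluster))
  }
  spots
}

#' Kinetic fractions inside clusters, outside, and in control spots
#'
#' A trajectory is "inside" when its mean position falls within any
#' cluster disc, "control" when it falls within a control spot, and
#' "outside" otherwise. Bound fractions (first kinetic bin) are computed
#' per field, and enrichment folds inside/outside and inside/control are
#' propagated from the across-field standard deviations.
#'
#' @param meanPos trajectory mean positions ([meanPositions()]).
#' @param assignedD per-trajectory diffusion coefficients (same order as
#'   `meanPos`).
#' @param field per-trajectory field labels.
#' @param clusters,controlSpots tables with `x`, `y`, `radius`.
#' @param bins a [KineticBins-class] object.
#' @return list with `fractions` (per-zone mean/sd of the bound
#'   fraction), `folds` (inside/outside, inside/control), and the
#'   per-trajectory `zone`.
#' @export
insideOutsideKinetics <- function(meanPos, assignedD, field, clusters,
                                  controlSpots, bins) {
  stopifnot(nrow(meanPos) == length(assignedD),
            length(assignedD) == length(field))
  inDisc <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(rep(FALSE, nrow(meanPos)))
    sapply(seq_len(nrow(meanPos)), function(i)
      any(sqrt((tab$x - meanPos$x[i])^2 +
               (tab$y - meanPos$y[i])^2) <= tab$radius))
  }
  inside <- inDisc(clusters)
  inCtrl <- !inside & inDisc(controlSpots)
  zone <- ifelse(inside, "inside", ifelse(inCtrl, "control", "outside"))
  bound <- binAssign(assignedD, bins) == 1L
  zones <- c("inside", "outside", "control")
  stats <- lapply(zones, function(z) {
    sel <- zone == z
    if (!any(sel)) return(c(mean = NA_real_, sd = NA_real_))
    bf <- tapply(bound[sel], field[sel], mean)
    c(mean = mean(bf), sd = if (length(bf) > 1) sd(bf) else 0)
  })
  names(stats) <- zones
  fr <- do.call(rbind, stats)
  if (!any(zone == "inside")) stop("no trajectories inside clusters")
  folds <- list(
    insideOutside = foldChange(fr["inside", "mean"], fr["outside", "mean"],
                               fr["inside", "sd"], fr["outside", "sd"]),
    insideControl = if (any(zone == "control"))
      foldChange(fr["inside", "mean"], fr["control", "mean"],
                 fr["inside", "sd"], fr["control", "sd"]) else NULL)
  list(fractions = fr, folds = folds, zone = zone)
}
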