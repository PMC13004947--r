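## MS2/MCP transcription-burst analysis: spot segmentation, paired
## trace extraction, burst segmentation, loading rates, and normalized
## cross-correlation with control-sphere nulls.

#' Centered moving average
#'
#' @param x numeric vector.
#' @param window odd window length in samples (default 3); 1 disables.
#' @return smoothed vector, same length (edges use the available
#'   samples).
#' @export
movingAverage <- function(x, window = 3) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Segment the MS2 transcription spot in one volume
#'
#' Per-slice difference of Gaussians (sigmas 1.5 and 6 pixels),
#' percentile threshold, removal of objects below `minVoxels` voxels and
#' of objects whose centroid lies outside the nuclear labels; per
#' nucleus the brightest surviving object is kept and its
#' intensity-weighted centroid returned.
#'
#' @param volume 3D array (Z, Y, X), MCP channel.
#' @param nuclearLabels integer 3D array of nucleus labels (0 =
#'   outside).
#' @param percentile DoG threshold percentile (default 0.999).
#' @param sigmas DoG sigmas, pixels (low, high).
#' @param minVoxels minimal object size (default 6).
#' @param voxelSize um per voxel (z, y, x).
#' @return data.frame, one row per nucleus with a detected spot:
#'   `nucleus`, voxel indices `zVox`, `yVox`, `xVox` (fractional,
#'   weighted centroid), positions `z`, `y`, `x` in um, and
#'   `intensity`; zero rows when nothing survives (a trace gap).
#' @export
segmentMs2Spot <- function(volume, nuclearLabels, percentile = 0.999,
                           sigmas = c(1.5, 6), minVoxels = 6,
                           voxelSize = c(0.3, 0.108, 0.108)) {
  stopifnot(identical(dim(volume), dim(nuclearLabels)))
  dog <- volume
  for (z in seq_len(dim(volume)[1]))
    dog[z, , ] <- EBImage::gblur(volume[z, , ], sigma = sigmas[1]) -
      EBImage::gblur(volume[z, , ], sigma = sigmas[2])
  thr <- quantile(dog, percentile)
  binary <- dog >= thr
  cc <- EBImage::bwlabel(binary)
  empty <- data.frame(nucleus = integer(0), zVox = numeric(0),
                      yVox = numeric(0), xVox = numeric(0), z = numeric(0),
                      y = numeric(0), x = numeric(0), intensity = numeric(0))
  if (max(cc) == 0) return(empty)
  out <- NULL
  for (k in seq_len(max(cc))) {
    w <- which(cc == k)
    if (length(w) < minVoxels) next
    co <- arrayInd(w, dim(volume))
    wt <- volume[w]
    cz <- sum(co[, 1] * wt) / sum(wt)
    cy <- sum(co[, 2] * wt) / sum(wt)
    cx <- sum(co[, 3] * wt) / sum(wt)
    nuc <- nuclearLabels[round(cz), round(cy), round(cx)]
    if (nuc == 0) next                       # cytoplasmic object
    out <- rbind(out, data.frame(nucleus = nuc, zVox = cz, yVox = cy,
                                 xVox = cx, z = (cz - 0.5) * voxelSize[1],
                                 y = (cy - 0.5) * voxelSize[2],
                                 x = (cx - 0.5) * voxelSize[3],
                                 intensity = sum(wt)))
  }
  if (is.null(out)) return(empty)
  ## brightest spot per nucleus
  out <- out[order(out$nucleus, -out$intensity), ]
  out[!duplicated(out$nucleus), , drop = FALSE]
}

## pixel offsets of a disc of the given diameter (pixels)
discOffsets <- function(diameterPx = 11) {
  r <- diameterPx / 2
  g <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  g[sqrt(g$dy^2 + g$dx^2) <= r, ]
}

#' Extract paired MCP / RNAPII intensity traces at a tracked spot
#'
#' Per frame: both channels are max-projected over `projSlices` z-slices
#' centered on the spot's z; the RNAPII signal is the integrated
#' intensity in a disc of `discDiameterPx` pixels (1.2 um at 0.108 um
#' pixels) around the spot, normalized to the nuclear mean to give
#' enrichment; the MCP value is the brightest 2 x 2 pixel square inside
#' the disc window. Missing spot frames are linearly interpolated for
#' gaps of up to `maxGap` consecutive frames, longer gaps split the
#' trace. Both channels are smoothed with a centered moving average.
#'
#' @param mcpStack,rnapiiStack 4D arrays (T, Z, Y, X).
#' @param spotTrack data.frame with columns `frame`, `zVox`, `yVox`,
#'   `xVox` (may skip frames).
#' @param nuclearMask logical (Z, Y, X) mask for background
#'   normalization.
#' @param frameInterval s between volumes (default 9).
#' @param discDiameterPx disc diameter, pixels (default 11).
#' @param projSlices z-slices in the max projection (default 3).
#' @param smoothWindow moving-average window, samples (default 3).
#' @param maxGap longest interpolatable gap, frames (default 2).
#' @return list of trace data.frames (`time`, `mcp`, `rnapii`,
#'   `clipped`), one per contiguous segment.
#' @export
extractTraces <- function(mcpStack, rnapiiStack, spotTrack, nuclearMask,
                          frameInterval = 9, discDiameterPx = 11,
                          projSlices = 3, smoothWindow = 3, maxGap = 2) {
  nT <- dim(mcpStack)[1]
  d <- dim(mcpStack)[2:4]
  off <- discOffsets(discDiameterPx)
  hz <- floor(projSlices / 2)
  one <- function(fr, zv, yv, xv) {
    zs <- max(1, round(zv) - hz):min(d[1], round(zv) + hz)
    mpM <- apply(mcpStack[fr, zs, , , drop = FALSE], c(3, 4), max)
    mpR <- apply(rnapiiStack[fr, zs, , , drop = FALSE], c(3, 4), max)
    maskYX <- apply(nuclearMask[zs, , , drop = FALSE], c(2, 3), any)
    ys <- round(yv) + off$dy; xs <- round(xv) + off$dx
    ok <- ys >= 1 & ys <= d[2] & xs >= 1 & xs <= d[3]
    disc <- cbind(ys[ok], xs[ok])
    rInt <- sum(mpR[disc])
    nucMean <- mean(mpR[maskYX])
    rEnr <- rInt / (sum(ok) * nucMean)
    ## brightest 2x2 square inside the disc window
    best <- -Inf
    for (i in which(ok)) {
      y0 <- ys[i]; x0 <- xs[i]
      if (y0 + 1 > d[2] || x0 + 1 > d[3]) next
      s <- sum(mpM[y0:(y0 + 1), x0:(x0 + 1)])
      if (s > best) best <- s
    }
    c(mcp = best, rnapii = rEnr, clipped = as.numeric(any(!ok)))
  }
  vals <- matrix(NA_real_, nT, 3,
                 dimnames = list(NULL, c("mcp", "rnapii", "clipped")))
  for (i in seq_len(nrow(spotTrack))) {
    fr <- spotTrack$frame[i]
    vals[fr, ] <- one(fr, spotTrack$zVox[i], spotTrack$yVox[i],
                      spotTrack$xVox[i])
  }
  present <- which(!is.na(vals[, 1]))
  if (!length(present)) stop("spot track covers no frames")
  ## split at gaps longer than maxGap, interpolate shorter ones
  segBreaks <- which(diff(present) > maxGap + 1)
  segStart <- c(1, segBreaks + 1)
  segEnd <- c(segBreaks, length(present))
  lapply(seq_along(segStart), function(s) {
    fr <- present[segStart[s]]:present[segEnd[s]]
    v <- vals[fr, , drop = FALSE]
    for (j in 1:2) {
      have <- !is.na(v[, j])
      if (sum(have) >= 2 && any(!have))
        v[, j] <- approx(fr[have], v[have, j], xout = fr)$y
    }
    data.frame(time = (fr - 1) * frameInterval,
               mcp = movingAverage(v[, 1], smoothWindow),
               rnapii = movingAverage(v[, 2], smoothWindow),
               clipped = !is.na(v[, 3]) & v[, 3] > 0)
  })
}

#' Segment transcription bursts from a paired trace
#'
#' Burst boundaries are the local minima of the (already smoothed) MCP
#' trace, with trace endpoints counting as boundaries; minima require a
#' prominence of at least `prominence` times the trace range. A
#' candidate segment is a burst when its internal MCP peak rises above
#' its boundary values by the same prominence and it lasts longer than
#' `minDuration`. Per burst, the loading rate is the least-squares slope
#' of the RNAPII enrichment from burst start to the frame of its
#' maximum.
#'
#' @param trace data.frame with `time` (s), `mcp`, `rnapii`.
#' @param minDuration minimal burst duration, s (default 30; bursts must
#'   be strictly longer).
#' @param prominence minima/peak prominence as a fraction of the MCP
#'   range (default 0.05).
#' @param samplingInterval s between samples (default 9).
#' @return data.frame per burst: `start`, `end`, `duration` (s),
#'   `maxRnapii`, `loadingRate` (enrichment/s).
#' @export
segmentBursts <- function(trace, minDuration = 30, prominence = 0.05,
                          samplingInterval = 9) {
  if (nrow(trace) < 5) stop("trace shorter than 5 samples")
  m <- trace$mcp
  n <- length(m)
  rng <- diff(range(m))
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), maxRnapii = numeric(0),
                      loadingRate = numeric(0))
  if (rng == 0) return(empty)
  cand <- which(m[2:(n - 1)] < m[1:(n - 2)] & m[2:(n - 1)] <= m[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    min(max(m[1:i]), max(m[i:n])) - m[i] >= prominence * rng
  }, logical(1))
  bounds <- sort(unique(c(1L, cand[keep], n)))
  thr <- min(m) + prominence * rng       # baseline activity threshold
  out <- NULL
  for (k in seq_len(length(bounds) - 1)) {
    seg <- bounds[k]:bounds[k + 1]
    active <- seg[m[seg] > thr]
    if (length(active) < 2) next
    i0 <- min(active); i1 <- max(active)
    dur <- (i1 - i0) * samplingInterval
    if (dur <= minDuration) next
    iMax <- (i0:i1)[which.max(trace$rnapii[i0:i1])]
    rise <- i0:iMax
    rate <- if (length(rise) >= 2)
      unname(coef(lm(trace$rnapii[rise] ~ trace$time[rise]))[2])
    else NA_real_
    out <- rbind(out, data.frame(start = trace$time[i0],
                                 end = trace$time[i1], duration = dur,
                                 maxRnapii = max(trace$rnapii[i0:i1]),
                                 loadingRate = rate))
  }
  if (is.null(out)) empty else out
}

#' Normalized full cross-correlation of two traces
#'
#' Both traces are mean-centered; the full discrete linear
#' cross-correlation is normalized by `n * sd(a) * sd(b)` (population
#' standard deviations), so the lag-0 value equals the Pearson
#' correlation coefficient. A peak at positive lag `k` means `b` lags
#' `a` by `k` samples.
#'
#' @param a,b equal-length numeric traces (length >= 3, nonzero
#'   variance).
#' @return data.frame with `lag` (-(n-1)..(n-1)) and `cc`.
#' @export
crossCorrelate <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("traces must have equal length")
  if (n < 3) stop("traces must have length >= 3")
  ac <- a - mean(a); bc <- b - mean(b)
  sa <- sqrt(mean(ac^2)); sb <- sqrt(mean(bc^2))
  if (sa == 0 || sb == 0) stop("zero-variance input")
  lags <- -(n - 1):(n - 1)
  cc <- vapply(lags, function(k) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    sum(ac[i[ok]] * bc[j[ok]])
  }, numeric(1))
  data.frame(lag = lags, cc = cc / (n * sa * sb))
}

#' Cross-correlations against control regions
#'
#' Places `nControls` disc-shaped control regions of the same size as
#' the locus disc, uniformly inside the nuclear mask and overlapping
#' neither the tracked spot (at any frame) nor each other, extracts
#' their RNAPII enrichment traces and cross-correlates each against the
#' MCP trace. Under the null of no locus-specific RNAPII enrichment the
#' control lag-0 correlations scatter around zero.
#'
#' @param rnapiiStack 4D array (T, Z, Y, X).
#' @param mcpTrace numeric MCP trace (length T).
#' @param spotTrack data.frame with `frame`, `zVox`, `yVox`, `xVox`.
#' @param nuclearMask logical (Z, Y, X).
#' @param nControls number of control regions (default 10).
#' @param discDiameterPx disc diameter, pixels.
#' @param projSlices z-slices in the max projection.
#' @param seed integer seed.
#' @param maxAttempts placement budget.
#' @return list with `lag0` (control lag-0 correlations), `centers`
#'   (placed control centers, pixels) and `cc` (list of full
#'   correlation tables). Fewer controls than requested triggers a
#'   warning.
#' @export
controlSphereCC <- function(rnapiiStack, mcpTrace, spotTrack, nuclearMask,
                            nControls = 10, discDiameterPx = 11,
                            projSlices = 3, seed = 1L, maxAttempts = 2000) {
  set.seed(seed)
  d <- dim(rnapiiStack)[2:4]
  maskYX <- apply(nuclearMask, c(2, 3), any)
  inside <- which(maskYX, arr.ind = TRUE)
  rpx <- discDiameterPx / 2
  centers <- NULL
  attempts <- 0
  while ((is.null(centers) || nrow(centers) < nControls) &&
         attempts < maxAttempts) {
    attempts <- attempts + 1
    p <- inside[sample.int(nrow(inside), 1), ]
    dSpot <- sqrt((spotTrack$yVox - p[1])^2 + (spotTrack$xVox - p[2])^2)
    if (any(dSpot < discDiameterPx)) next
    if (!is.null(centers)) {
      dc <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
      if (any(dc < discDiameterPx)) next
    }
    centers <- rbind(centers, p)
  }
  if (is.null(centers)) stop("could not place any control region")
  if (nrow(centers) < nControls)
    warning(sprintf("placed %d of %d control regions", nrow(centers),
                    nControls))
  off <- discOffsets(discDiameterPx)
  hz <- floor(projSlices / 2)
  zRef <- round(median(spotTrack$zVox))
  zs <- max(1, zRef - hz):min(d[1], zRef + hz)
  ccs <- lapply(seq_len(nrow(centers)), function(i) {
    ys <- centers[i, 1] + off$dy; xs <- centers[i, 2] + off$dx
    ok <- ys >= 1 & ys <= d[2] & xs >= 1 & xs <= d[3]
    disc <- cbind(ys[ok], xs[ok])
    tr <- vapply(seq_len(dim(rnapiiStack)[1]), function(t) {
      mp <- apply(rnapiiStack[t, zs, , , drop = FALSE], c(3, 4), max)
      sum(mp[disc]) / (sum(ok) * mean(mp[maskYX]))
    }, numeric(1))
    crossCorrelate(tr, mcpTrace)
  })
  lag0 <- vapply(ccs, function(x) x$cc[x$lag == 0], numeric(1))
  list(lag0 = lag0, centers = centers, cc = ccs)
}
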