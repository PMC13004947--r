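## Small 3D morphology toolkit for Z x Y x X volumes: shifted-array
## min/max filters, reconstruction by dilation, Otsu thresholding,
## local maxima and a seeded watershed. EBImage supplies the 2D median
## filter, Gaussian blur and 3D connected-component labelling.

## offsets of a Euclidean ball of radius r (voxels), as an integer matrix
ballOffsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, ])
}

crossOffsets <- function() {
  rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
        c(0, 0, -1), c(0, 0, 1))
}

## shift a 3D array by (dz, dy, dx), padding with `pad`
shift3 <- function(vol, dz, dy, dx, pad) {
  d <- dim(vol)
  out <- array(pad, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- vol[zs - dz, ys - dy, xs - dx]
  out
}

## grayscale erosion (fun = pmin, pad = Inf) or dilation (pmax, -Inf)
morphFilter3 <- function(vol, offsets, fun = pmin, pad = Inf) {
  out <- vol
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- fun(out, shift3(vol, o[1], o[2], o[3], pad))
  }
  out
}

greyErode3 <- function(vol, radius = 2)
  morphFilter3(vol, ballOffsets(radius), pmin, Inf)

greyDilate3 <- function(vol, offsets = crossOffsets())
  morphFilter3(vol, offsets, pmax, -Inf)

## morphological reconstruction of `mask` from `marker` by iterative
## geodesic dilation (6-connectivity); marker must be <= mask
reconstructByDilation <- function(marker, mask, maxIter = 1000) {
  cur <- pmin(marker, mask)
  for (i in seq_len(maxIter)) {
    nxt <- pmin(greyDilate3(cur), mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

## Otsu threshold on a numeric vector (256-bin histogram)
otsuThreshold <- function(v, nBins = 256) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(v, breaks = seq(rng[1], rng[2], length.out = nBins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[length(cm)]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

## 2D median filter applied per z-slice (EBImage constant-time median);
## values are rescaled into [0, 1] for the filter and restored after
medianFilterSlices <- function(vol, radius = 1) {
  mx <- max(vol)
  if (mx <= 0) return(vol)
  out <- vol
  for (z in seq_len(dim(vol)[1]))
    out[z, , ] <- EBImage::medianFilter(vol[z, , ] / mx, radius) * mx
  out
}

## local maxima of vol within `binary`, greedily thinned so kept maxima
## are at least minSep voxels apart (Euclidean, isotropic voxel units)
localMaxima3 <- function(vol, binary, minSep = 3) {
  nb <- ballOffsets(1)
  mx <- morphFilter3(vol, nb, pmax, -Inf)
  cand <- which(binary & vol >= mx & vol > 0)
  if (!length(cand)) return(matrix(numeric(0), 0, 3))
  d <- dim(vol)
  co <- arrayInd(cand, d)
  ord <- order(vol[cand], decreasing = TRUE)
  co <- co[ord, , drop = FALSE]
  keep <- logical(nrow(co))
  for (i in seq_len(nrow(co))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kk <- co[keep, , drop = FALSE]
    if (all(rowSums(sweep(kk, 2, co[i, ])^2) >= minSep^2)) keep[i] <- TRUE
  }
  co[keep, , drop = FALSE]
}

## marker-based watershed: voxels of `binary` are visited in decreasing
## `intensity` order and join the label of an already-labelled 6-neighbor;
## repeated passes handle voxels whose neighbors are labelled later
seededWatershed <- function(intensity, binary, markers) {
  d <- dim(intensity)
  labels <- array(0L, d)
  if (nrow(markers) > 0)
    labels[markers] <- seq_len(nrow(markers))
  idx <- which(binary)
  idx <- idx[order(intensity[idx], decreasing = TRUE)]
  co <- arrayInd(idx, d)
  nb <- crossOffsets()[-1, ]
  repeat {
    changed <- FALSE
    for (i in seq_along(idx)) {
      if (labels[idx[i]] != 0L) next
      p <- co[i, ]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        l <- labels[q[1], q[2], q[3]]
        if (l != 0L) { labels[idx[i]] <- l; changed <- TRUE; break }
      }
    }
    if (!changed) break
  }
  ## binary components that contained no marker (flat plateaus) keep
  ## their own labels via connected components
  rest <- binary & labels == 0L
  if (any(rest)) {
    cc <- EBImage::bwlabel(rest)
    labels[rest] <- max(labels) + cc[rest]
  }
  labels * binary
}
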