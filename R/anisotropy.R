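## Displacement-angle anisotropy: turning angles between consecutive
## jumps and the backward/forward fold statistic.

#' Turning angles between consecutive displacements
#'
#' For every interior localization the angle between the incoming and
#' outgoing jump vectors is computed from the normalized dot product
#' (clamped to \[-1, 1\] before `acos`), in degrees in \[0, 180\]. Pairs in
#' which either jump is shorter than `minJump` are skipped, and
#' trajectories carrying the excluded state label (chromatin-bound, by
#' default) are removed first, since immobile molecules would bias the
#' angle distribution.
#'
#' @param tracks trajectory table (`trajectory`, `frame`, `x`, `y` in um).
#' @param minJump minimal jump length, um (default 0.2).
#' @param stateLabels optional per-trajectory state labels, named by
#'   trajectory id.
#' @param exclude state label(s) to drop (default `"bound"`).
#' @return data.frame with columns `trajectory` and `angle` (degrees);
#'   may have zero rows.
#' @export
computeAngles <- function(tracks, minJump = 0.2, stateLabels = NULL,
                          exclude = "bound") {
  if (!is.null(stateLabels)) {
    drop <- names(stateLabels)[stateLabels %in% exclude]
    tracks <- tracks[!as.character(tracks$trajectory) %in% drop, ]
  }
  if (nrow(tracks) == 0)
    return(data.frame(trajectory = numeric(0), angle = numeric(0)))
  tracks <- tracks[order(tracks$trajectory, tracks$frame), ]
  same <- c(FALSE, diff(as.integer(factor(tracks$trajectory))) == 0)
  dx <- c(NA, diff(tracks$x)); dy <- c(NA, diff(tracks$y))
  dx[!same] <- NA; dy[!same] <- NA
  ## jump i ends at row i; consecutive pair = jumps ending at rows i, i+1
  v1x <- dx[-length(dx)]; v1y <- dy[-length(dy)]
  v2x <- dx[-1]; v2y <- dy[-1]
  id <- tracks$trajectory[-1]
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  ok <- !is.na(n1) & !is.na(n2) & n1 >= minJump & n2 >= minJump
  ct <- (v1x * v2x + v1y * v2y)[ok] / (n1[ok] * n2[ok])
  ct <- pmin(1, pmax(-1, ct))
  data.frame(trajectory = id[ok], angle = acos(ct) * 180 / pi)
}

#' Fold-anisotropy statistic
#'
#' Probability of a backward turning angle (within `window` degrees of
#' 180) divided by the probability of a forward one (within `window`
#' degrees of 0); both windows are closed. An isotropic walk gives 1;
#' confined motion gives values above 1. With no forward-window angles
#' the ratio is undefined and `NA` is returned with a warning.
#'
#' @param angles numeric vector of angles in degrees, or the data.frame
#'   from [computeAngles()].
#' @param window half-width of the forward/backward windows, degrees.
#' @return the fold-anisotropy ratio (possibly `NA`).
#' @export
foldAnisotropy <- function(angles, window = 30) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (length(angles) == 0) stop("no angles")
  back <- mean(angles >= 180 - window & angles <= 180)
  fwd <- mean(angles >= 0 & angles <= window)
  if (fwd == 0) {
    warning("no forward-window angles; fold-anisotropy undefined")
    return(NA_real_)
  }
  back / fwd
}

#' Subsampling uncertainty of the fold-anisotropy
#'
#' Recomputes the fold-anisotropy on `nBoot` random subsamples of
#' `floor(frac * N)` angles drawn without replacement, and reports their
#' mean and standard deviation.
#'
#' @param angles angles in degrees (vector or [computeAngles()] output).
#' @param frac subsample fraction (default 0.5).
#' @param nBoot number of subsamples (default 20).
#' @param seed integer seed.
#' @param window window half-width, degrees.
#' @return list with `mean`, `sd` and the per-subsample `values`.
#' @export
bootstrapAnisotropy <- function(angles, frac = 0.5, nBoot = 20, seed = 1L,
                                window = 30) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (length(angles) < 2) stop("need at least 2 angles")
  m <- floor(frac * length(angles))
  if (m < 10) warning("subsample smaller than 10 angles")
  set.seed(seed)
  vals <- vapply(seq_len(nBoot), function(i) {
    sub <- angles[sample.int(length(angles), m)]
    suppressWarnings(foldAnisotropy(sub, window))
  }, numeric(1))
  list(mean = mean(vals, na.rm = TRUE), sd = sd(vals), values = vals)
}
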