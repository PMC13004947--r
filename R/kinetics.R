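## Diffusion-state inference on a fixed log-spaced grid.
##
## A trajectory's squared 2D displacements are treated as independent
## exponentials with mean 4 * (D * dt + sigma_loc^2); occupancies over the
## grid are estimated by finite-mixture expectation-maximization.

#' Log-spaced diffusion-coefficient grid
#'
#' @param n number of grid points (default 100).
#' @param min,max grid range in um^2/s (defaults 0.001 and 100).
#' @return numeric vector of `n` log-spaced diffusion coefficients.
#' @examples
#' g <- diffusionGrid()
#' range(g)  # 0.001 .. 100
#' @export
diffusionGrid <- function(n = 100, min = 0.001, max = 100) {
  stopifnot(n >= 2, min > 0, max > min)
  exp(seq(log(min), log(max), length.out = n))
}

## per-trajectory sufficient statistics: number of jumps and sum of squared
## jump lengths. Assumes gap-free, frame-ordered tracks (readTrajectories
## validates this).
jumpStats <- function(tracks) {
  stopifnot(all(c("trajectory", "frame", "x", "y") %in% names(tracks)))
  tracks <- tracks[order(tracks$trajectory, tracks$frame), ]
  same <- c(FALSE, diff(tracks$trajectory) == 0)
  dx <- c(NA, diff(tracks$x))[same]
  dy <- c(NA, diff(tracks$y))[same]
  id <- tracks$trajectory[same]
  r2 <- dx^2 + dy^2
  ids <- unique(tracks$trajectory)
  nJumps <- tabulate(match(id, ids), nbins = length(ids))
  s <- numeric(length(ids))
  if (length(r2)) {
    g <- rowsum(r2, as.character(id))
    s[match(rownames(g), as.character(ids))] <- g[, 1]
  }
  data.frame(trajectory = ids, nJumps = nJumps, sumR2 = s)
}

#' Per-grid-point log-likelihood of one trajectory
#'
#' Log-likelihood of a trajectory's 2D jumps under each grid diffusion
#' coefficient, treating squared jump lengths as independent exponentials
#' with mean `4 * (D * dt + sigmaLoc^2)`. Depends on the positions only
#' through displacements, hence is invariant under global translation.
#'
#' @param traj data.frame with columns `frame`, `x`, `y` (one trajectory),
#'   or a two-column matrix of positions in um.
#' @param grid diffusion-coefficient grid, um^2/s.
#' @param sigmaLoc localization noise sd, um.
#' @param frameInterval frame interval, s.
#' @return numeric vector of log-likelihoods, one per grid point.
#' @export
trajectoryGridLogLik <- function(traj, grid = diffusionGrid(),
                                 sigmaLoc = 0.030, frameInterval = 0.01) {
  if (is.matrix(traj)) traj <- data.frame(x = traj[, 1], y = traj[, 2])
  dx <- diff(traj$x); dy <- diff(traj$y)
  if (length(dx) < 1) stop("trajectory has no jumps")
  r2 <- dx^2 + dy^2
  m <- 4 * (grid * frameInterval + sigmaLoc^2)
  -length(r2) * log(m) - sum(r2) / m
}

#' Estimate diffusion-coefficient occupancies by grid-mixture EM
#'
#' Fits a finite mixture over a fixed log-spaced grid of diffusion
#' coefficients to a set of trajectories by expectation-maximization,
#' starting from uniform weights. Per-trajectory posterior
#' responsibilities are retained for state assignment. The localization
#' noise is treated as known (it is estimated separately from slow
#' chromatin-tethered tracks, see [estimateLocalizationError()]).
#'
#' @param tracks trajectory table (`trajectory`, `frame`, `x`, `y` in um).
#' @param grid diffusion-coefficient grid, um^2/s.
#' @param sigmaLoc localization noise sd, um (default 0.030).
#' @param frameInterval frame interval, s.
#' @param maxIter maximum EM iterations (default 200).
#' @param tol stop when the log-likelihood gain drops below this.
#' @return an [OccupancyProfile-class] object.
#' @examples
#' sim <- simulateTrajectories(smtSimConfig(nTrajectories = 200, seed = 2))
#' prof <- estimateOccupancy(sim$tracks)
#' prof
#' @export
estimateOccupancy <- function(tracks, grid = diffusionGrid(),
                              sigmaLoc = 0.030, frameInterval = 0.01,
                              maxIter = 200, tol = 1e-8) {
  if (is.null(tracks) || nrow(tracks) == 0) stop("no trajectories supplied")
  st <- jumpStats(tracks)
  if (nrow(st) == 0 || all(st$nJumps == 0)) stop("no jumps in input")
  st <- st[st$nJumps > 0, ]
  m <- 4 * (grid * frameInterval + sigmaLoc^2)
  ## n_i x n_grid log-likelihood, from sufficient statistics
  L <- outer(st$nJumps, log(m), `*`) * -1 - outer(st$sumR2, 1 / m)
  K <- length(grid)
  w <- rep(1 / K, K)
  llTrace <- numeric(0)
  resp <- NULL
  for (it in seq_len(maxIter)) {
    A <- sweep(L, 2, log(w), `+`)
    mx <- apply(A, 1, max)
    E <- exp(A - mx)
    rs <- rowSums(E)
    resp <- E / rs
    ll <- sum(log(rs) + mx)
    llTrace <- c(llTrace, ll)
    w <- colMeans(resp)
    w <- w / sum(w)
    if (it > 1 && llTrace[it] - llTrace[it - 1] < tol) break
  }
  rownames(resp) <- st$trajectory
  new("OccupancyProfile", grid = grid, occupancy = w / sum(w),
      localizationSigma = sigmaLoc, nTrajectories = nrow(st),
      responsibilities = resp, logLik = llTrace)
}

## discrete Gaussian smoothing of an occupancy curve, sd in grid points
smoothOccupancy <- function(occ, sdPoints = 3) {
  if (sdPoints <= 0) return(occ)
  half <- ceiling(4 * sdPoints)
  k <- exp(-(seq(-half, half))^2 / (2 * sdPoints^2))
  k <- k / sum(k)
  n <- length(occ)
  pad <- c(rep(occ[1], half), occ, rep(occ[n], half))
  as.numeric(stats::filter(pad, k, sides = 2))[half + seq_len(n)]
}

#' Divide an occupancy profile into kinetic-state bins
#'
#' Boundaries are placed at the local minima of the smoothed occupancy
#' curve: the first state runs from the low end of the grid to the first
#' minimum, the last from the last minimum to the high end, and middle
#' states between consecutive minima. A unimodal profile yields a single
#' bin. Minima must have a prominence of at least `prominence` times the
#' curve maximum, which guards against EM graininess.
#'
#' @param profile an [OccupancyProfile-class] object.
#' @param smoothPoints sd of the Gaussian smoothing kernel, in grid
#'   points (default 3).
#' @param prominence minimal minima prominence as a fraction of the peak
#'   occupancy (default 0.01).
#' @param labels optional state names; by default three bins are named
#'   bound/intermediate/fast.
#' @return a [KineticBins-class] object.
#' @export
findStateBoundaries <- function(profile, smoothPoints = 3,
                                prominence = 0.01, labels = NULL) {
  stopifnot(is(profile, "OccupancyProfile"))
  occ <- smoothOccupancy(profile@occupancy, smoothPoints)
  n <- length(occ)
  cand <- which(occ[2:(n - 1)] < occ[1:(n - 2)] &
                occ[2:(n - 1)] <= occ[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    promL <- max(occ[1:i]) - occ[i]
    promR <- max(occ[i:n]) - occ[i]
    min(promL, promR) >= prominence * max(occ)
  }, logical(1))
  cand <- cand[keep]
  ## one boundary per valley: successive minima with no intervening peak
  ## (rising above both by the prominence) belong to the same valley
  groups <- list()
  for (i in cand) {
    if (length(groups)) {
      j <- tail(groups[[length(groups)]], 1)
      ridge <- max(occ[j:i]) - max(occ[i], occ[j])
      if (ridge < prominence * max(occ)) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], i)
        next
      }
    }
    groups[[length(groups) + 1]] <- i
  }
  ## a flat valley admits many minima; the boundary is placed at the
  ## midpoint of its low-occupancy floor (maximum margin to both modes)
  cutIdx <- vapply(groups, function(g) {
    floorLev <- min(occ[g]) + prominence * max(occ)
    lo <- min(g); hi <- max(g)
    while (lo > 1 && occ[lo - 1] <= floorLev) lo <- lo - 1
    while (hi < n && occ[hi + 1] <= floorLev) hi <- hi + 1
    as.integer(round((lo + hi) / 2))
  }, integer(1))
  cut <- profile@grid[cutIdx]
  k <- length(cut) + 1L
  if (is.null(labels)) {
    labels <- switch(as.character(k),
                     "1" = "all",
                     "2" = c("slow", "fast"),
                     "3" = c("bound", "intermediate", "fast"),
                     paste0("state", seq_len(k)))
  }
  stopifnot(length(labels) == k)
  new("KineticBins", boundaries = cut, labels = labels,
      gridRange = range(profile@grid))
}

#' Assign a single diffusion coefficient to each trajectory
#'
#' The assigned coefficient is the geometric mean of the grid values
#' weighted by the trajectory's posterior responsibilities,
#' `exp(sum(w_i * log(D_i)))`. Multiplying all grid values by a constant
#' multiplies every assignment by the same constant.
#'
#' @param x an [OccupancyProfile-class] object, or a responsibility
#'   matrix (rows = trajectories, normalized).
#' @param grid grid values; taken from the profile when `x` is one.
#' @return named numeric vector of diffusion coefficients, um^2/s.
#' @export
assignTrajectoryD <- function(x, grid = NULL) {
  if (is(x, "OccupancyProfile")) {
    grid <- x@grid
    x <- x@responsibilities
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("all-zero responsibility row")
  x <- x / rs
  setNames(as.numeric(exp(x %*% log(grid))), rownames(x))
}

## bin index (1..k) of each diffusion coefficient under a KineticBins object
binAssign <- function(D, bins) {
  findInterval(D, c(-Inf, bins@boundaries, Inf))
}

#' Occupancy mass per kinetic bin
#'
#' Sums the posterior occupancy of an [OccupancyProfile-class] within
#' each kinetic bin. This is the state-array notion of a kinetic
#' fraction (e.g. the bound fraction is the occupancy below the first
#' boundary) and is the estimator used for headline fractions; unlike
#' per-trajectory assignment counts it is not biased by the shrinkage
#' of short-track assignments toward the slow modes.
#'
#' @param profile an [OccupancyProfile-class] object.
#' @param bins a [KineticBins-class] object.
#' @return named numeric vector of per-bin occupancy mass (sums to 1).
#' @export
occupancyFractions <- function(profile, bins) {
  idx <- findInterval(profile@grid, c(-Inf, bins@boundaries, Inf))
  m <- vapply(seq_along(bins@labels), function(k)
    sum(profile@occupancy[idx == k]), numeric(1))
  setNames(m, bins@labels)
}

#' Per-field kinetic fractions from per-field occupancy profiles
#'
#' Fits an occupancy profile per field of view (with the state
#' boundaries frozen, e.g. on the pooled or vehicle profile) and
#' reports each field's per-bin occupancy mass plus the mean and
#' standard deviation across fields.
#'
#' @param tracks trajectory table.
#' @param field per-trajectory field labels, named by trajectory id (or
#'   aligned with the unique trajectory ids of `tracks`).
#' @param bins a [KineticBins-class] object (typically from the pooled
#'   profile).
#' @param grid,sigmaLoc,frameInterval passed to [estimateOccupancy()].
#' @return a list with `perField`, `mean`, `sd`, `nFields`, as in
#'   [computeFractions()].
#' @export
computeOccupancyFractions <- function(tracks, field, bins,
                                      grid = diffusionGrid(),
                                      sigmaLoc = 0.030,
                                      frameInterval = 0.01) {
  ids <- unique(tracks$trajectory)
  if (is.null(names(field))) names(field) <- ids
  fieldOf <- field[as.character(tracks$trajectory)]
  fr <- t(vapply(unique(field), function(f) {
    sub <- tracks[fieldOf == f, ]
    if (nrow(sub) == 0) stop("field with zero trajectories: ", f)
    prof <- estimateOccupancy(sub, grid, sigmaLoc, frameInterval)
    occupancyFractions(prof, bins)
  }, numeric(length(bins@labels))))
  rownames(fr) <- unique(field)
  perField <- data.frame(field = rownames(fr), fr, row.names = NULL,
                         check.names = FALSE)
  list(perField = perField, mean = colMeans(fr), sd = apply(fr, 2, sd),
       nFields = nrow(fr))
}

#' Per-field kinetic fractions from assigned-coefficient counts
#'
#' Counts trajectories per kinetic bin within each field of view and
#' reports per-field fractions plus their mean and standard deviation
#' across fields. Note that for very short trajectories the
#' geometric-mean assignment shrinks toward the slow modes, which can
#' bias count-based fractions; [computeOccupancyFractions()] is the
#' estimator of choice for headline fractions.
#'
#' @param assignedD per-trajectory diffusion coefficients, um^2/s.
#' @param field per-trajectory field-of-view labels.
#' @param bins a [KineticBins-class] object.
#' @return a list with `perField` (data.frame of fractions, one row per
#'   field), `mean`, `sd` (named by state) and `nFields`.
#' @export
computeFractions <- function(assignedD, field, bins) {
  stopifnot(length(assignedD) == length(field))
  b <- binAssign(assignedD, bins)
  k <- length(bins@labels)
  if (!is.factor(field)) field <- factor(field)   # keep declared empty fields
  tab <- table(field, factor(b, levels = seq_len(k)))
  tot <- rowSums(tab)
  if (any(tot == 0)) stop("field with zero trajectories: ",
                          paste(rownames(tab)[tot == 0], collapse = ", "))
  fr <- sweep(unclass(tab), 1, tot, `/`)
  colnames(fr) <- bins@labels
  perField <- data.frame(field = rownames(tab), fr, row.names = NULL,
                         check.names = FALSE)
  list(perField = perField,
       mean = colMeans(fr),
       sd = apply(fr, 2, sd),
       nFields = nrow(fr))
}

#' Estimate the localization error from slow trajectories
#'
#' Selects the trajectories ranking in the lowest `percentile` (default
#' 5th) of mobility and computes the mean of their consecutive
#' displacements, `m`. For an immobile emitter localized twice with
#' per-axis noise sd `sigma`, the displacement length is Rayleigh with
#' mean `sigma * sqrt(pi)`, so the estimate is `m / sqrt(pi)`.
#'
#' Selecting the slowest tracks on the very displacements that are then
#' averaged would bias the estimate low (the selected tracks are the
#' ones whose noise happened to be small; even alternating jumps stay
#' coupled through their shared localizations). When no external
#' `assignedD` is supplied, each trajectory's jumps are therefore split
#' into a leading half used for ranking and a trailing half used for
#' the mean displacement, with one jump skipped in between so the two
#' halves share no localization -- selection and measurement are then
#' strictly independent.
#'
#' @param tracks trajectory table.
#' @param assignedD optional externally assigned per-trajectory
#'   diffusion coefficients (named by trajectory id); when given,
#'   selection uses them and the mean displacement uses all jumps.
#' @param percentile quantile defining the slow subset (default 0.05).
#' @param frameInterval frame interval, s (unused in the split-half
#'   path; kept for interface symmetry).
#' @return localization error sd, um.
#' @export
estimateLocalizationError <- function(tracks, assignedD = NULL,
                                      percentile = 0.05,
                                      frameInterval = 0.01) {
  ids <- unique(tracks$trajectory)
  if (length(ids) < 100) stop("need at least 100 trajectories")
  tracks <- tracks[order(tracks$trajectory, tracks$frame), ]
  same <- c(FALSE, diff(as.integer(factor(tracks$trajectory))) == 0)
  dx <- c(NA, diff(tracks$x))[same]
  dy <- c(NA, diff(tracks$y))[same]
  id <- tracks$trajectory[same]
  r <- sqrt(dx^2 + dy^2)
  jumpIdx <- sequence(rle(as.character(id))$lengths)
  if (is.null(assignedD)) {
    ## split-half with a buffer jump: rank on the leading half, measure
    ## on the trailing half (disjoint localizations)
    nJ <- ave(jumpIdx, as.character(id), FUN = length)
    half <- floor((nJ - 1) / 2)
    sel <- jumpIdx <= half            # ranking jumps
    meas <- jumpIdx >= half + 2       # measurement jumps
    rank <- tapply(r[sel]^2, id[sel], mean)
    thr <- quantile(rank, percentile, na.rm = TRUE)
    slow <- names(rank)[!is.na(rank) & rank <= thr]
    if (length(slow) < 10) stop("too few slow trajectories")
    m <- mean(r[meas & as.character(id) %in% slow])
  } else {
    thr <- quantile(assignedD, percentile)
    slow <- names(assignedD)[assignedD <= thr]
    if (is.null(slow)) slow <- as.character(ids)[assignedD <= thr]
    if (length(slow) < 10) stop("too few slow trajectories")
    m <- mean(r[as.character(id) %in% slow])
  }
  m / sqrt(pi)
}
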