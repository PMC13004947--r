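## Synthetic single-molecule trajectories: Brownian mixtures inside a
## circular nucleus, with localization noise and geometric track lengths.

#' Simulate single-molecule trajectories from a Brownian state mixture
#'
#' Each trajectory is assigned one kinetic state (no within-track
#' switching) and performs a 2D Brownian walk with per-axis step variance
#' `2 * D * dt`, reflected at the circular nuclear boundary. Independent
#' Gaussian localization noise of sd `localizationSigma` is added to every
#' localization (and reflected back inside the nucleus, so all reported
#' positions lie within the mask). Track lengths are geometric with a
#' minimum of 3 localizations, emulating exponential photobleaching.
#' When `nBoundHotspots > 0`, trajectories of the first (slowest) state
#' are started inside randomly placed circular hotspots.
#'
#' @param config an [SmtSimConfig-class] object.
#' @return a list with elements
#'   \describe{
#'     \item{tracks}{data.frame with columns `trajectory`, `frame`, `x`,
#'       `y` (um), one row per localization.}
#'     \item{truth}{data.frame with per-trajectory ground truth: `trajectory`,
#'       `state` (integer), `D` (um^2/s), `nFrames`.}
#'     \item{hotspots}{data.frame of hotspot centers and radius (um), or
#'       NULL.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulateTrajectories(smtSimConfig(nTrajectories = 50, seed = 7))
#' head(sim$tracks)
#' @export
simulateTrajectories <- function(config) {
  stopifnot(is(config, "SmtSimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- as.integer(config@nTrajectories)
  R <- config@nucleusRadius
  dt <- config@frameInterval

  state <- sample.int(length(config@stateFractions), n, replace = TRUE,
                      prob = config@stateFractions)
  D <- config@stateD[state]

  ## geometric track length, minimum 3 localizations
  p <- 1 / max(config@meanTrackLength - 2, 1)
  len <- 3L + rgeom(n, min(p, 1))
  len <- pmin(len, 200L)
  maxLen <- max(len)

  ## hotspots for bound (first-state) trajectories
  hotspots <- NULL
  if (config@nBoundHotspots > 0) {
    hr <- config@hotspotRadius
    hu <- runif(config@nBoundHotspots); ha <- runif(config@nBoundHotspots)
    hRad <- (R - hr) * sqrt(hu); hAng <- 2 * pi * ha
    hotspots <- data.frame(x = hRad * cos(hAng), y = hRad * sin(hAng),
                           radius = hr)
  }

  ## starting positions: uniform in the disc (or a hotspot for bound tracks)
  u <- runif(n); a <- runif(n)
  x0 <- R * sqrt(u) * cos(2 * pi * a)
  y0 <- R * sqrt(u) * sin(2 * pi * a)
  if (!is.null(hotspots)) {
    sel <- state == 1L
    if (any(sel)) {
      hs <- sample.int(nrow(hotspots), sum(sel), replace = TRUE)
      uu <- runif(sum(sel)); aa <- runif(sum(sel))
      x0[sel] <- hotspots$x[hs] + hotspots$radius[1] * sqrt(uu) * cos(2 * pi * aa)
      y0[sel] <- hotspots$y[hs] + hotspots$radius[1] * sqrt(uu) * sin(2 * pi * aa)
    }
  }

  stepSd <- sqrt(2 * D * dt)
  X <- matrix(NA_real_, n, maxLen)
  Y <- matrix(NA_real_, n, maxLen)
  X[, 1] <- x0; Y[, 1] <- y0
  x <- x0; y <- y0
  for (t in 2:maxLen) {
    x <- x + rnorm(n) * stepSd
    y <- y + rnorm(n) * stepSd
    r <- sqrt(x^2 + y^2)
    out <- r > R
    if (any(out)) {            # radial reflection at the nuclear envelope
      f <- (2 * R - r[out]) / r[out]
      f <- pmax(f, 0)          # guard extreme excursions
      x[out] <- x[out] * f
      y[out] <- y[out] * f
    }
    X[, t] <- x; Y[, t] <- y
  }

  ## localization noise, reflected back inside the mask
  if (config@localizationSigma > 0) {
    X <- X + rnorm(length(X)) * config@localizationSigma
    Y <- Y + rnorm(length(Y)) * config@localizationSigma
    r <- sqrt(X^2 + Y^2)
    out <- !is.na(r) & r > R
    if (any(out)) {
      f <- (2 * R - r[out]) / r[out]
      X[out] <- X[out] * pmax(f, 0)
      Y[out] <- Y[out] * pmax(f, 0)
    }
  }

  keep <- which(col(X) <= len[row(X)])
  ord <- order(row(X)[keep], col(X)[keep])
  keep <- keep[ord]
  tracks <- data.frame(trajectory = row(X)[keep],
                       frame = col(X)[keep],
                       x = X[keep], y = Y[keep])
  truth <- data.frame(trajectory = seq_len(n), state = state, D = D,
                      nFrames = len)
  list(tracks = tracks, truth = truth, hotspots = hotspots, config = config)
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage name to a
#' per-stage seed below 2^31, so that all pipeline randomness flows from
#' one seed without stages sharing streams.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
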