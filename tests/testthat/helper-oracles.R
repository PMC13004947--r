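## Independent brute-force oracles used across the suite.

## density-reachability oracle: core points, their connected components,
## and for border points the set of admissible clusters
bruteDensityOracle <- function(points, eps = 0.2, minSamples = 15) {
  n <- nrow(points)
  d <- as.matrix(dist(cbind(points$x, points$y)))
  nb <- d <= eps
  core <- rowSums(nb) >= minSamples
  comp <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (comp[i] != 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cl
      stack <- c(stack, which(core & nb[v, ] & comp == 0L))
    }
  }
  admissible <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    sort(unique(comp[core & nb[i, ]]))
  })
  list(core = core, coreComp = comp, admissible = admissible)
}

## pixel count of a disc of the given diameter, by exhaustive scan
discCountOracle <- function(diameterPx) {
  r <- diameterPx / 2
  cnt <- 0L
  for (dy in -20:20) for (dx in -20:20)
    if (sqrt(dy^2 + dx^2) <= r) cnt <- cnt + 1L
  cnt
}

## Monte-Carlo sd of a ratio of two Gaussians
mcRatioSd <- function(a, sdA, b, sdB, n = 1e5, seed = 99) {
  set.seed(seed)
  sd(rnorm(n, a, sdA) / rnorm(n, b, sdB))
}

## squared-displacement statistics of a trajectory table
trackJumps <- function(tracks) {
  tracks <- tracks[order(tracks$trajectory, tracks$frame), ]
  same <- c(FALSE, diff(tracks$trajectory) == 0)
  dx <- c(NA, diff(tracks$x))[same]
  dy <- c(NA, diff(tracks$y))[same]
  cbind(dx, dy)
}
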