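test_that("grid likelihood peaks at r^2 / (4 dt) for a single jump", {
  r <- 0.3
  traj <- data.frame(frame = 1:2, x = c(0, r), y = c(0, 0))
  dense <- diffusionGrid(3000, 0.01, 10)
  ll <- trajectoryGridLogLik(traj, dense, sigmaLoc = 0, frameInterval = 0.01)
  expect_equal(dense[which.max(ll)], r^2 / (4 * 0.01), tolerance = 0.01)
})

test_that("grid likelihood is monotone for zero jumps and translation-invariant", {
  traj <- data.frame(frame = 1:5, x = rep(1, 5), y = rep(2, 5))
  ll <- trajectoryGridLogLik(traj, sigmaLoc = 0.03)
  expect_equal(which.max(ll), 1L)          # smallest grid D wins
  set.seed(1)
  traj2 <- data.frame(frame = 1:6, x = cumsum(rnorm(6, 0, 0.1)),
                      y = cumsum(rnorm(6, 0, 0.1)))
  shifted <- transform(traj2, x = x + 5.3, y = y - 2.1)
  expect_equal(trajectoryGridLogLik(traj2), trajectoryGridLogLik(shifted))
  expect_error(trajectoryGridLogLik(data.frame(frame = 1, x = 0, y = 0)),
               "no jumps")
})

test_that("the diffusion grid spans 0.001-100 um^2/s with 100 points", {
  g <- diffusionGrid()
  expect_length(g, 100)
  expect_equal(range(g), c(0.001, 100))
  expect_true(all(diff(log(g)) > 0))
  expect_equal(var(diff(log(g))), 0, tolerance = 1e-20)
})

test_that("EM occupancy recovers single- and two-state simulations", {
  ## D well above the 0.03 um localization floor is localizable on the grid
  cfg <- smtSimConfig(nTrajectories = 5000, stateFractions = 1,
                      stateD = 0.5, localizationSigma = 0.03,
                      meanTrackLength = 8, seed = 21)
  prof <- estimateOccupancy(simulateTrajectories(cfg)$tracks,
                            sigmaLoc = 0.03)
  g <- gridValues(prof)
  nearMode <- abs(log10(g) - log10(0.5)) <= 0.5     # half a decade
  expect_gte(sum(occupancy(prof)[nearMode]), 0.9)
  expect_true(all(diff(prof@logLik) > -1e-6))       # EM monotone
  expect_equal(sum(occupancy(prof)), 1, tolerance = 1e-9)

  cfg2 <- smtSimConfig(nTrajectories = 4000, stateFractions = c(0.5, 0.5),
                       stateD = c(0.005, 5), localizationSigma = 0.03,
                       meanTrackLength = 8, seed = 22)
  prof2 <- estimateOccupancy(simulateTrajectories(cfg2)$tracks,
                             sigmaLoc = 0.03)
  split <- sqrt(0.005 * 5)
  lowMass <- sum(occupancy(prof2)[gridValues(prof2) < split])
  expect_lt(abs(lowMass - 0.5), 0.05)
  expect_error(estimateOccupancy(NULL), "no trajectories")
})

test_that("state boundaries fall at occupancy minima", {
  g <- diffusionGrid()
  tri <- exp(-(log10(g) + 2.5)^2 / 0.08) + exp(-(log10(g) + 0.7)^2 / 0.08) +
    exp(-(log10(g) - 0.9)^2 / 0.08)
  prof <- new("OccupancyProfile", grid = g, occupancy = tri / sum(tri),
              localizationSigma = 0.03, nTrajectories = 1,
              responsibilities = matrix(1), logLik = 0)
  bins <- findStateBoundaries(prof, smoothPoints = 1)
  expect_length(binBoundaries(bins), 2)
  expect_identical(binLabels(bins), c("bound", "intermediate", "fast"))
  ## boundaries near the analytic valley midpoints
  expect_equal(log10(binBoundaries(bins)), c(-1.6, 0.1), tolerance = 0.15)

  uni <- exp(-(log10(g))^2 / 0.5)
  prof2 <- new("OccupancyProfile", grid = g, occupancy = uni / sum(uni),
               localizationSigma = 0.03, nTrajectories = 1,
               responsibilities = matrix(1), logLik = 0)
  bins2 <- findStateBoundaries(prof2, smoothPoints = 1)
  expect_length(binBoundaries(bins2), 0)
  expect_identical(binLabels(bins2), "all")
})

test_that("geometric-mean assignment is exact and scale-covariant", {
  g <- c(0.01, 0.5, 1)
  expect_equal(unname(assignTrajectoryD(matrix(c(0, 1, 0), 1), g)), 0.5)
  expect_equal(unname(assignTrajectoryD(matrix(c(0.5, 0, 0.5), 1),
                                        c(0.01, 0.5, 1))), 0.1)
  set.seed(3)
  resp <- matrix(runif(50), 10, 5)
  resp <- resp / rowSums(resp)
  grid <- diffusionGrid(5, 0.01, 10)
  expect_equal(assignTrajectoryD(resp, grid * 7),
               assignTrajectoryD(resp, grid) * 7)
  expect_error(assignTrajectoryD(matrix(0, 1, 3), g), "all-zero")
})

test_that("per-field fractions sum to one and flag empty fields", {
  bins <- new("KineticBins", boundaries = c(0.05, 1),
              labels = c("bound", "intermediate", "fast"),
              gridRange = c(0.001, 100))
  D <- c(0.01, 0.02, 0.3, 5, 0.01, 9)
  f <- c(1, 1, 1, 2, 2, 2)
  fr <- computeFractions(D, f, bins)
  expect_true(all(abs(rowSums(fr$perField[, -1]) - 1) < 1e-9))
  expect_equal(fr$perField$bound, c(2 / 3, 1 / 3))
  allBound <- computeFractions(rep(0.01, 4), c(1, 1, 2, 2), bins)
  expect_true(all(allBound$perField$bound == 1))
  expect_error(computeFractions(D, factor(f, levels = 1:3), bins), "zero")
})

test_that("localization error recovers 30 nm from immobile emitters", {
  cfg <- smtSimConfig(nTrajectories = 1500, stateFractions = 1, stateD = 0,
                      localizationSigma = 0.030, meanTrackLength = 8,
                      seed = 31)
  sim <- simulateTrajectories(cfg)
  est <- estimateLocalizationError(sim$tracks,
                                   assignedD = rep(1e-3, 1500) +
                                     1e-6 * seq_len(1500))
  expect_equal(est, 0.030, tolerance = 0.002 / 0.03)

  ## zero-noise immobile emitters give zero
  cfg0 <- smtSimConfig(nTrajectories = 200, stateFractions = 1, stateD = 0,
                       localizationSigma = 0, seed = 32)
  sim0 <- simulateTrajectories(cfg0)
  expect_equal(estimateLocalizationError(sim0$tracks,
                                         assignedD = runif(200, 1e-3, 2e-3)),
               0)

  ## adding fast trajectories leaves the slow-subset estimate stable
  cfgF <- smtSimConfig(nTrajectories = 1500, stateFractions = 1, stateD = 5,
                       localizationSigma = 0.03, seed = 33)
  simF <- simulateTrajectories(cfgF)
  simF$tracks$trajectory <- simF$tracks$trajectory + 10000
  mixed <- rbind(sim$tracks, simF$tracks)
  estMixed <- estimateLocalizationError(
    mixed, assignedD = setNames(c(rep(1e-3, 1500), rep(5, 1500)),
                                c(1:1500, 10001:11500)))
  expect_lt(abs(estMixed - 0.030), 0.002)
  expect_error(estimateLocalizationError(sim0$tracks[1:20, ]), "100")
})

test_that("simulated bound trajectories are assigned below the bound boundary", {
  cfg <- smtSimConfig(nTrajectories = 6000,
                      stateFractions = c(0.5, 0.2, 0.3),
                      stateD = c(0.002, 0.2, 8), localizationSigma = 0.03,
                      meanTrackLength = 8, seed = 41)
  sim <- simulateTrajectories(cfg)
  prof <- estimateOccupancy(sim$tracks, sigmaLoc = 0.03)
  bins <- findStateBoundaries(prof)
  D <- assignTrajectoryD(prof)
  boundIds <- sim$truth$trajectory[sim$truth$D == 0.002]
  isBound <- polclust:::binAssign(D[names(D) %in% boundIds], bins) == 1L
  expect_gte(mean(isBound), 0.95)
})

test_that("occupancy-mass fractions sum to one and respect frozen bins", {
  g <- diffusionGrid(10, 0.001, 100)
  occ <- rep(0.1, 10)
  prof <- new("OccupancyProfile", grid = g, occupancy = occ,
              localizationSigma = 0.03, nTrajectories = 1,
              responsibilities = matrix(1), logLik = 0)
  bins <- new("KineticBins", boundaries = g[4] * 1.01,
              labels = c("slow", "fast"), gridRange = range(g))
  f <- occupancyFractions(prof, bins)
  expect_equal(unname(f), c(0.4, 0.6))
  expect_equal(sum(f), 1)

  cfg <- smtSimConfig(nTrajectories = 600, stateFractions = c(0.5, 0.5),
                      stateD = c(0.005, 5), localizationSigma = 0.03,
                      seed = 61)
  sim <- simulateTrajectories(cfg)
  ids <- unique(sim$tracks$trajectory)
  field <- setNames(rep(1:3, length.out = length(ids)), ids)
  bins2 <- new("KineticBins", boundaries = 0.15,
               labels = c("slow", "fast"), gridRange = c(0.001, 100))
  fr <- computeOccupancyFractions(sim$tracks, field, bins2)
  expect_equal(fr$nFields, 3)
  expect_true(all(abs(rowSums(fr$perField[, -1]) - 1) < 1e-9))
  expect_lt(abs(fr$mean[["slow"]] - 0.5), 0.1)
})
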