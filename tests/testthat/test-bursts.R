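## shared fixture: ellipsoidal nucleus labels in a small volume
mkLabeledNucleus <- function(shape = c(8L, 48L, 48L)) {
  cfg <- nucleusMovieConfig(shape = c(1L, shape), nClusters = 0, nHlbs = 0,
                            backgroundNoiseSigma = 0, seed = 1)
  mv <- simulateNucleusMovie(cfg)
  list(mask = mv$mask, labels = array(as.integer(mv$mask), dim(mv$mask)))
}

test_that("MS2 spot segmentation finds the brightest in-nucleus object", {
  nuc <- mkLabeledNucleus()
  vol <- array(10, dim(nuc$mask))
  vol <- polclust:::addBlob(vol, c(1.2, 2.6, 2.6), 0.15, 500,
                            c(0.3, 0.108, 0.108))
  sp <- segmentMs2Spot(vol, nuc$labels, percentile = 0.999)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$y - 2.6), 0.11)
  expect_lt(abs(sp$x - 2.6), 0.11)

  ## a bright object outside the nuclear labels is ignored
  volOut <- array(10, dim(nuc$mask))
  volOut <- polclust:::addBlob(volOut, c(1.2, 0.1, 0.1), 0.15, 500,
                               c(0.3, 0.108, 0.108))
  expect_equal(nrow(segmentMs2Spot(volOut, nuc$labels, 0.999)), 0)

  ## of two spots in one nucleus, the brighter is selected
  vol2 <- polclust:::addBlob(vol, c(1.2, 3.6, 3.6), 0.15, 250,
                             c(0.3, 0.108, 0.108))
  sp2 <- segmentMs2Spot(vol2, nuc$labels, 0.999)
  expect_equal(nrow(sp2), 1)
  expect_lt(abs(sp2$y - 2.6), 0.11)
})

test_that("objects below six voxels are removed as noise", {
  nuc <- mkLabeledNucleus()
  vol <- array(10, dim(nuc$mask))
  vol[4, 24, 24] <- 5000                    # single hot voxel
  sp <- segmentMs2Spot(vol, nuc$labels, percentile = 0.9999)
  expect_equal(nrow(sp), 0)
})

test_that("disc integration matches the brute-force pixel-count oracle", {
  expect_equal(nrow(polclust:::discOffsets(11)), discCountOracle(11))
  expect_equal(nrow(polclust:::discOffsets(7)), discCountOracle(7))
  ## uniform RNAPII channel gives enrichment exactly 1
  nuc <- mkLabeledNucleus()
  nT <- 8
  stackR <- array(50, c(nT, dim(nuc$mask)))
  stackM <- array(1, c(nT, dim(nuc$mask)))
  spot <- data.frame(frame = 1:nT, zVox = 4, yVox = 24, xVox = 24)
  tr <- extractTraces(stackM, stackR, spot, nuc$mask, smoothWindow = 1)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$rnapii, rep(1, nT), tolerance = 1e-12)
  expect_false(any(tr[[1]]$clipped))
})

test_that("extracted traces follow the generator's coupled signal", {
  cfg <- polIISimConfig(kOn = 1, kOff = 0, tOn = 2, seed = 9)
  out <- generateCoupledTraces(cfg, noiseSigma = 0, nNuclei = 1, seed = 9,
                               duration = 4 * 60)
  mcp <- out[[1]]$trace$mcp
  nT <- length(mcp)
  nuc <- mkLabeledNucleus(c(6L, 48L, 48L))
  stackM <- array(10, c(nT, dim(nuc$mask)))
  stackR <- array(50, c(nT, dim(nuc$mask)))
  for (t in seq_len(nT))
    stackM[t, , , ] <- polclust:::addBlob(stackM[t, , , ],
                                          c(0.9, 2.6, 2.6), 0.12,
                                          5 * mcp[t], c(0.3, 0.108, 0.108))
  spot <- data.frame(frame = 1:nT, zVox = 3, yVox = 24, xVox = 24)
  tr <- extractTraces(stackM, stackR, spot, nuc$mask, smoothWindow = 1)[[1]]
  expect_gt(cor(tr$mcp, mcp), 0.99)
})

test_that("trace gaps are interpolated up to two frames, then split", {
  nuc <- mkLabeledNucleus(c(4L, 32L, 32L))
  stackR <- array(50, c(10, dim(nuc$mask)))
  stackM <- array(1, c(10, dim(nuc$mask)))
  spot <- data.frame(frame = c(1:3, 6:10), zVox = 2, yVox = 16, xVox = 16)
  tr <- extractTraces(stackM, stackR, spot, nuc$mask, smoothWindow = 1,
                      maxGap = 2)
  expect_length(tr, 1)                       # 2-frame gap interpolated
  expect_equal(nrow(tr[[1]]), 10)
  tr2 <- extractTraces(stackM, stackR, spot, nuc$mask, smoothWindow = 1,
                       maxGap = 1)
  expect_length(tr2, 2)                      # split at the longer gap
})

test_that("burst segmentation durations and exclusions are as designed", {
  tt <- seq(0, 60) * 9
  tri <- pmax(0, 90 - abs(tt - 270)) / 90
  trc <- data.frame(time = tt, mcp = tri, rnapii = tri)
  b <- segmentBursts(trc)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$duration - 180), 18 + 1e-9)
  ## a 27 s burst is excluded by the > 30 s rule
  short <- rep(0, 61); short[30:33] <- c(0.5, 1, 0.5, 0)
  b2 <- segmentBursts(data.frame(time = tt, mcp = short, rnapii = short))
  expect_equal(nrow(b2), 0)
  ## monotone flat trace has no bursts
  flat <- data.frame(time = tt, mcp = rep(2, 61), rnapii = rep(1, 61))
  expect_equal(nrow(segmentBursts(flat)), 0)
  expect_error(segmentBursts(trc[1:4, ]), "5 samples")
})

test_that("cross-correlation matches the Pearson oracle at lag zero", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    a <- rnorm(n); b <- rnorm(n)
    cc <- crossCorrelate(a, b)
    expect_lt(abs(cc$cc[cc$lag == 0] - cor(a, b)), 1e-9)
  }
})

test_that("cross-correlation identities: self, delay, swap symmetry", {
  set.seed(32)
  a <- rnorm(40)
  self <- crossCorrelate(a, a)
  expect_equal(self$cc[self$lag == 0], 1, tolerance = 1e-9)
  expect_true(all(abs(self$cc) <= 1 + 1e-9))
  k <- 5
  b <- c(rep(0, k), a[1:(40 - k)])         # b delayed by k samples
  cc <- crossCorrelate(a[10:40], b[10:40])
  expect_equal(cc$lag[which.max(cc$cc)], k)
  x <- rnorm(25); y <- rnorm(25)
  ab <- crossCorrelate(x, y); ba <- crossCorrelate(y, x)
  expect_equal(ab$cc, rev(ba$cc), tolerance = 1e-12)
  expect_error(crossCorrelate(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(crossCorrelate(rnorm(5), rnorm(6)), "equal length")
})

test_that("control regions separate locus-specific from null enrichment", {
  nuc <- mkLabeledNucleus(c(6L, 48L, 48L))
  nT <- 30
  set.seed(33)
  mcp <- pmax(0, sin(seq(0, 3 * pi, length.out = nT))) + 0.05
  ## locus-only RNAPII enrichment tracking the MCP signal
  stackR <- array(50, c(nT, dim(nuc$mask)))
  for (t in seq_len(nT))
    stackR[t, , , ] <- polclust:::addBlob(stackR[t, , , ],
                                          c(0.9, 2.6, 2.6), 0.15,
                                          200 * mcp[t], c(0.3, 0.108, 0.108))
  spot <- data.frame(frame = 1:nT, zVox = 3, yVox = 24, xVox = 24)
  locusTr <- extractTraces(array(1, c(nT, dim(nuc$mask))), stackR, spot,
                           nuc$mask, smoothWindow = 1)[[1]]
  locusCC <- crossCorrelate(locusTr$rnapii, mcp)
  ctrl <- controlSphereCC(stackR, mcp, spot, nuc$mask, nControls = 5,
                          seed = 7)
  expect_gt(locusCC$cc[locusCC$lag == 0], 0.9)
  ## control regions never show the positive locus coupling (background
  ## normalization couples them weakly and negatively to the locus)
  expect_true(all(ctrl$lag0 < locusCC$cc[locusCC$lag == 0] - 0.5))
  ## same seed, same placements
  ctrl2 <- controlSphereCC(stackR, mcp, spot, nuc$mask, nControls = 5,
                           seed = 7)
  expect_identical(ctrl$centers, ctrl2$centers)

  ## null construction: spatially uniform RNAPII with iid noise makes the
  ## locus and control correlations indistinguishable
  set.seed(34)
  stackU <- array(500 + rnorm(nT * prod(dim(nuc$mask))),
                  c(nT, dim(nuc$mask)))
  locusU <- extractTraces(array(1, c(nT, dim(nuc$mask))), stackU, spot,
                          nuc$mask, smoothWindow = 1)[[1]]
  ccU <- crossCorrelate(locusU$rnapii, mcp)
  ctrlU <- controlSphereCC(stackU, mcp, spot, nuc$mask, nControls = 5,
                           seed = 8)
  expect_lt(abs(ccU$cc[ccU$lag == 0]), 0.6)
  expect_true(all(abs(ctrlU$lag0) < 0.6))
})
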