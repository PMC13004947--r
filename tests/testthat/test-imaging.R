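mkNucleus <- function(shape = c(12L, 48L, 48L), baseline = 100) {
  cfg <- nucleusMovieConfig(shape = c(1L, shape), nClusters = 0, nHlbs = 0,
                            backgroundNoiseSigma = 0, baseline = baseline,
                            seed = 1)
  mv <- simulateNucleusMovie(cfg)
  list(vol = mv$movie[1, , , ], mask = mv$mask, cfg = cfg)
}

addBlobAt <- function(vol, center, sigma, amplitude,
                      vs = c(0.3, 0.108, 0.108)) {
  polclust:::addBlob(vol, center, sigma, amplitude, vs)
}

test_that("nuclear normalization gives unit mean enrichment", {
  nuc <- mkNucleus()
  enr <- normalizeNucleus(nuc$vol, nuc$mask)
  expect_true(all(enr[nuc$mask] == 1))
  expect_true(all(enr[!nuc$mask] == 0))
  ## with a blob the in-mask mean is still exactly 1
  vol <- addBlobAt(nuc$vol, c(1.8, 2.6, 2.6), 0.25, 300)
  enr2 <- normalizeNucleus(vol, nuc$mask)
  expect_equal(mean(enr2[nuc$mask]), 1, tolerance = 1e-9)
  ## direct arithmetic oracle for the blob peak enrichment
  peakOracle <- max(vol[nuc$mask]) / mean(vol[nuc$mask])
  expect_equal(max(enr2), peakOracle, tolerance = 1e-12)
  expect_error(normalizeNucleus(nuc$vol, array(FALSE, dim(nuc$vol))),
               "empty")
})

test_that("segmentation finds single and touching blobs", {
  nuc <- mkNucleus()
  vol <- addBlobAt(nuc$vol, c(1.8, 2.6, 2.6), 0.3, 200)
  enr <- normalizeNucleus(vol, nuc$mask)
  seg <- segmentClusters(enr, nuc$mask)
  expect_equal(nrow(seg$clusters), 1)
  expect_lt(abs(seg$clusters$z - 1.8), 0.3)    # one z-slice
  expect_lt(abs(seg$clusters$y - 2.6), 0.11)
  expect_lt(abs(seg$clusters$x - 2.6), 0.11)

  ## two blobs 1.5 um apart are split by the watershed
  vol2 <- addBlobAt(nuc$vol, c(1.8, 2.6, 1.8), 0.3, 200)
  vol2 <- addBlobAt(vol2, c(1.8, 2.6, 3.3), 0.3, 200)
  seg2 <- segmentClusters(normalizeNucleus(vol2, nuc$mask), nuc$mask)
  expect_equal(nrow(seg2$clusters), 2)
  expect_equal(sort(round(seg2$clusters$x, 1)), c(1.8, 3.3), tolerance = 0.1)
})

test_that("segmentation count matches ground truth for separated blobs", {
  for (seed in c(101, 202, 303)) {
    cfg <- nucleusMovieConfig(shape = c(1L, 14L, 56L, 56L), nClusters = 4,
                              nHlbs = 0, backgroundNoiseSigma = 0,
                              clusterAmplitude = 4, clusterSigma = 0.22,
                              lifetimeMixture = c(0, 99, 99), seed = seed)
    mv <- simulateNucleusMovie(cfg)
    tt <- mv$truth
    sep <- min(dist(cbind(tt$z, tt$y, tt$x)))
    if (sep < 5 * 0.22) next           # only assert for separated layouts
    enr <- normalizeNucleus(mv$movie[1, , , ], mv$mask)
    seg <- segmentClusters(enr, mv$mask)
    expect_equal(nrow(seg$clusters), 4)
  }
})

test_that("HLB detection flags at most the two brightest overlapping blobs", {
  nuc <- mkNucleus(shape = c(12L, 64L, 64L))
  ## five dim blobs and three bright ones
  pos <- list(c(1.8, 2.0, 2.0), c(1.8, 2.0, 4.9), c(1.8, 4.9, 2.0),
              c(1.8, 4.9, 4.9), c(1.2, 3.4, 3.4),
              c(2.4, 2.0, 3.4), c(2.4, 4.9, 3.4), c(1.2, 3.4, 5.6))
  amp <- c(rep(150, 5), 900, 800, 700)
  vol <- nuc$vol
  for (i in seq_along(pos)) vol <- addBlobAt(vol, pos[[i]], 0.25, amp[i])
  enr <- normalizeNucleus(vol, nuc$mask)
  ## fixed binarization threshold: Otsu would drop the dim blobs when the
  ## top-hat histogram is dominated by the bright ones
  seg <- segmentClusters(enr, nuc$mask, threshold = 0.3)
  expect_equal(nrow(seg$clusters), 8)
  res <- detectHlbs(enr, seg, percentile = 0.995)
  expect_equal(nrow(res$hlbs), 2)       # <= 2 even with 3 bright blobs
  expect_equal(nrow(res$clusters), 6)
  ## the flagged ones are the two with highest mean enrichment
  expect_equal(sort(res$hlbs$meanEnrichment),
               sort(seg$clusters$meanEnrichment, decreasing = TRUE)[2:1])
  ## flat image has no HLBs
  nucFlat <- mkNucleus()
  enrF <- normalizeNucleus(nucFlat$vol, nucFlat$mask)
  segF <- segmentClusters(enrF, nucFlat$mask)
  resF <- detectHlbs(enrF, segF)
  expect_equal(nrow(resF$hlbs), 0)
})

test_that("enrichment filter is exact at the 1.65 threshold and monotone", {
  cl <- data.frame(cluster = 1:4, z = 0, y = 0, x = 0, nVoxels = 10,
                   volumeUm3 = 1,
                   meanEnrichment = c(1.60, 1.65, 1.70, 3),
                   integratedIntensity = 1, maxEnrichment = 3)
  kept <- filterByEnrichment(cl)
  expect_false(1 %in% kept$cluster)     # 1.60 removed
  expect_true(3 %in% kept$cluster)      # 1.70 kept
  expect_equal(nrow(filterByEnrichment(cl, 0)), 4)
  counts <- sapply(seq(0, 4, by = 0.5), function(th)
    nrow(filterByEnrichment(cl, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster density is count over volume", {
  expect_equal(clusterDensity(12, 100), 0.12)
  expect_equal(clusterDensity(0, 50), 0)
  expect_equal(clusterDensity(6, 50), 2 * clusterDensity(6, 100))
  expect_error(clusterDensity(3, 0), "volume")
})

test_that("lifetime tracking is exact on constructed detections", {
  det <- data.frame(frame = 1:10, z = 1.5, y = 2, x = 2)
  trk <- trackLifetimes(det, frameInterval = 10, nTotalFrames = 20)
  expect_equal(nrow(trk), 1)
  expect_equal(trk$lifetimeMin, 100 / 60)
  expect_equal(trk$normalizedLifetime, 0.5)
  ## a 0.9 um z-jump breaks the track (600 nm rule)
  det2 <- data.frame(frame = 1:6, z = c(1.5, 1.5, 1.5, 2.4, 2.4, 2.4),
                     y = 2, x = 2)
  trk2 <- trackLifetimes(det2, 10, 6)
  expect_equal(nrow(trk2), 2)
  expect_equal(trk2$nFrames, c(3, 3))
  ## a frame gap also terminates the track
  det3 <- data.frame(frame = c(1, 2, 4, 5), z = 1.5, y = 2, x = 2)
  trk3 <- trackLifetimes(det3, 10, 5)
  expect_equal(nrow(trk3), 2)
})

test_that("noise-free movie lifetimes are recovered exactly", {
  ## find a seed whose blobs stay mutually separated, then require
  ## exact track recovery on it
  for (seed in c(31, 32, 33, 34, 35)) {
    cfg <- nucleusMovieConfig(shape = c(10L, 12L, 56L, 56L), nClusters = 3,
                              nHlbs = 0, backgroundNoiseSigma = 0,
                              clusterAmplitude = 4, clusterSigma = 0.22,
                              lifetimeMixture = c(0.5, 0.4, 1), seed = seed)
    mv <- simulateNucleusMovie(cfg)
    tt <- mv$truth
    if (nrow(tt) > 1 && min(dist(cbind(tt$z, tt$y, tt$x))) < 1.2) next
    det <- segmentMovieClusters(mv$movie, mv$mask)
    trk <- trackLifetimes(det, cfg@frameInterval, dim(mv$movie)[1])
    expect_equal(nrow(trk), nrow(tt))
    expect_setequal(trk$nFrames, tt$nFrames)
    expect_setequal(trk$startFrame, tt$birthFrame)
    break
  }
})

test_that("the lifetime mixture fit recovers Gaussian populations", {
  lt <- sampleLifetimes(300, c(0.33, 2, 7), seed = 4, family = "gaussian")
  fit <- fitLifetimeMixture(lt)
  expect_lt(abs(mixtureWeights(fit)[2] - 0.67), 0.05)
  expect_lt(abs(mixtureMeans(fit)[1] / 2 - 1), 0.15)
  expect_lt(abs(mixtureMeans(fit)[2] / 7 - 1), 0.15)
  expect_equal(sum(mixtureWeights(fit)), 1, tolerance = 1e-9)
  ## deterministic
  fit2 <- fitLifetimeMixture(lt)
  expect_equal(mixtureWeights(fit), mixtureWeights(fit2))
  ## single-Gaussian data (degenerate path): the two components collapse
  ## onto the same population rather than inventing separated modes
  set.seed(44)
  one <- rnorm(200, 5, 0.5)
  fit1 <- fitLifetimeMixture(one)
  expect_lt(diff(mixtureMeans(fit1)), 3 * 0.5)
  expect_equal(sum(mixtureWeights(fit1)), 1, tolerance = 1e-9)
  expect_error(fitLifetimeMixture(rnorm(10, 5, 1)), "at least 20")
})

test_that("mixture weight uncertainty matches binomial resimulation", {
  w <- 0.67; n <- 300
  formulaSd <- sqrt(w * (1 - w) / n)
  set.seed(6)
  resim <- sd(rbinom(4000, n, w) / n)
  expect_lt(abs(formulaSd / resim - 1), 0.1)
  lt <- sampleLifetimes(n, c(0.33, 2, 7), seed = 8, family = "gaussian")
  fit <- fitLifetimeMixture(lt)
  expect_equal(fit@weightSd[2],
               sqrt(prod(mixtureWeights(fit)) / n), tolerance = 1e-12)
})

test_that("lifetime subsampling caps clusters per nucleus", {
  tr <- data.frame(track = 1:30, nucleus = rep(1:3, each = 10),
                   lifetimeMin = runif(30, 1, 10))
  expect_warning(sub <- subsampleLifetimes(tr, maxPerNucleus = 8, seed = 2),
                 "fewer than 5 nuclei")
  expect_equal(unname(table(sub$nucleus)), rep(8L, 3),
               ignore_attr = TRUE)
  expect_identical(suppressWarnings(subsampleLifetimes(tr, 8, seed = 2)),
                   sub)
})
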