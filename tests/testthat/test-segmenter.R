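test_that("radial symmetry peaks at dark-disk centers", {
  img <- matrix(1, 120, 120)
  expect_lt(max(abs(fastRadialSymmetry(img, c(6, 8, 10)))), 1e-12)
  expect_error(fastRadialSymmetry(img, integer(0)), "non-empty")

  disk <- 1 - 0.8 * (diskMask(120, 120, cbind(60, 60), 8) > 0)
  S <- fastRadialSymmetry(disk, c(6, 8, 10))
  peak <- which(S == max(S), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((peak - c(60, 60))^2)), 2)

  two <- 1 - 0.8 * (diskMask(140, 140, rbind(c(40, 40), c(100, 100)), 8) > 0)
  S2 <- fastRadialSymmetry(two, c(6, 8, 10))
  mk <- detectMarkers(S2, minDistance = 10, relThreshold = 0.5)
  expect_equal(nrow(mk), 2)
  d <- apply(mk, 1, function(p) min(sqrt(colSums((t(rbind(c(40, 40),
                                                  c(100, 100))) - p)^2))))
  expect_true(all(d < 2))
})

test_that("marker detection thresholds, suppresses and degrades gracefully", {
  m <- matrix(0, 60, 60); m[30, 30] <- 1
  mk <- detectMarkers(m, 10, 0.2)
  expect_equal(unname(mk[1, ]), c(30, 30))
  expect_equal(nrow(detectMarkers(matrix(0, 30, 30), 10, 0.2)), 0)
  # two peaks 5 px apart, min distance 10 -> one marker survives
  m2 <- matrix(0, 60, 60); m2[30, 30] <- 1; m2[30, 35] <- 0.9
  expect_equal(nrow(detectMarkers(m2, 10, 0.2)), 1)
  expect_error(detectMarkers(m, 10, 0), "relThreshold")
})

test_that("marker-controlled watershed grows one region per seeded nucleus", {
  s <- cleanSample(seed = 31, n = 2, size = 160)
  M <- estimateStainMatrix(sampleImage(s))
  # smoothed map, as in the full pipeline: chromatin texture otherwise
  # fragments the geodesic basins
  hema <- EBImage::gblur(separateHematoxylin(sampleImage(s), M), sigma = 2)
  gtc <- round(centroids(s))
  seg <- markerWatershed(hema, gtc)
  expect_equal(nucleiCount(seg), 2)
  # each region covers at least 70% of its nucleus and they are disjoint
  for (i in 1:2) {
    nuc <- nucleiMask(s) == nucleiMask(s)[gtc[i, 1], gtc[i, 2]]
    cover <- max(vapply(1:2, function(j)
      sum(labelMask(seg) == j & nuc) / sum(nuc), numeric(1)))
    expect_gt(cover, 0.7)
  }
  expect_equal(nucleiCount(markerWatershed(hema,
                                           matrix(integer(0), 0, 2))), 0)
  expect_error(markerWatershed(hema, cbind(1000, 10)), "bounds")
})

test_that("shape filtering removes small, elongated and off-range regions", {
  lab <- matrix(0L, 200, 200)
  lab[diskMask(200, 200, cbind(60, 60), 15) > 0] <- 1L   # round, area ~700
  lab[100, 30:190] <- 2L                                 # 1-px line
  lab[150:151, 150:154] <- 3L                            # 10 px^2 speck
  seg <- segmentationFromMask(lab)
  st <- regionStats(seg)
  expect_gt(st$roundness[1], 0.8)
  expect_gt(st$solidity[1], 0.9)
  expect_lt(st$roundness[2], 0.4)
  filt <- filterRegions(seg, areaRange = c(314, 4900), minRoundness = 0.4,
                        minSolidity = 0.7)
  expect_equal(nucleiCount(filt), 1)
  expect_equal(unname(round(centroids(filt)[1, ])), c(60, 60))
  # idempotence
  filt2 <- filterRegions(filt, areaRange = c(314, 4900), minRoundness = 0.4,
                         minSolidity = 0.7)
  expect_identical(labelMask(filt), labelMask(filt2))
  expect_error(filterRegions(seg, areaRange = c(10, 5)), "exceeds")
})

# unfiltered detection stage, for the marker-count inequality
markerWatershedFromSample <- function(s) {
  M <- estimateStainMatrix(sampleImage(s))
  hema <- separateHematoxylin(sampleImage(s), M)
  sm <- EBImage::gblur(hema, sigma = 2)
  frst <- EBImage::gblur(
    fastRadialSymmetry(max(sm) - sm, c(5, 10, 15, 20, 25, 30, 35)), sigma = 3)
  markerWatershed(sm, detectMarkers(frst, 10, 0.2))
}

test_that("clean well-separated nuclei are segmented perfectly", {
  s <- cleanSample(seed = 7, n = 8, size = 320)
  seg <- segmentNuclei(sampleImage(s))
  gt <- segmentationFromMask(nucleiMask(s))
  m <- matchNuclei(seg, gt)
  expect_equal(m$f1, 1)
  expect_gt(diceScore(labelMask(seg) > 0, nucleiMask(s) > 0), 0.85)
  # region count after filtering never exceeds the marker count
  expect_lte(nucleiCount(seg), nucleiCount(markerWatershedFromSample(s)))
})

test_that("segmentation is deterministic and a blank field yields no nuclei", {
  s <- cleanSample(seed = 9, n = 5, size = 256)
  a <- segmentNuclei(sampleImage(s))
  b <- segmentNuclei(sampleImage(s))
  expect_identical(labelMask(a), labelMask(b))
  white <- array(254, c(96, 96, 3))
  expect_equal(nucleiCount(segmentNuclei(white)), 0)
})

test_that("detected counts track the true count within 10% on clean fields", {
  for (sd in c(7, 21, 99)) {
    s <- cleanSample(seed = sd, n = 10, size = 384)
    seg <- segmentNuclei(sampleImage(s))
    n <- max(nucleiMask(s))
    expect_lte(abs(nucleiCount(seg) - n) / n, 0.1)
  }
})
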