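test_that("tiling uses floor division and records the cropped remainder", {
  g <- tileImage(matrix(0, 1000, 1000), 12)
  expect_equal(g$nTiles, 83 * 83)
  expect_equal(g$remainder, c(4, 4))
  expect_equal(tileImage(matrix(0, 24, 24), 12)$nTiles, 4)
  expect_error(tileImage(matrix(0, 10, 10), 12), "exceeds")
})

test_that("tile histograms count (t/m)^2 patches and concentrate for constant tiles", {
  withr::with_seed(21, {
    feats <- matrix(rnorm(1600), 200, 8)
    book <- buildCodebook(feats, 4, seed = 1, patchSize = 2L)
    h <- encodeTile(matrix(rnorm(144), 12, 12), book)
    expect_equal(sum(h), 36)                     # (12/2)^2
    hconst <- encodeTile(matrix(5, 12, 12), book)
    expect_equal(max(hconst), 36)                # all patches identical
    book4 <- buildCodebook(matrix(rnorm(320), 10, 32), 2, seed = 1,
                           patchSize = 4L)
    expect_equal(sum(encodeTile(matrix(rnorm(144), 12, 12), book4)), 9)
    book8 <- buildCodebook(matrix(rnorm(1280), 10, 128), 2, seed = 1,
                           patchSize = 8L)
    expect_error(encodeTile(matrix(0, 12, 12), book8), "divisible")
  })
})

test_that("whole-image encoding conserves histogram mass and matches per-tile calls", {
  withr::with_seed(22, {
    img <- matrix(rnorm(96 * 96), 96, 96)
    book <- buildCodebook(matrix(rnorm(800), 100, 8), 4, seed = 1,
                          patchSize = 2L)
    grid <- tileImage(img, 12)
    H <- encodeTiles(img, grid, book)
    expect_true(all(rowSums(H) == 36))
    # spot-check a few tiles against the scalar path
    for (i in c(1, 9, 37, grid$nTiles)) {
      ext <- noiseletHE:::.tileExtent(grid, i)
      expect_equal(H[i, ], encodeTile(img[ext$rows, ext$cols], book))
    }
  })
})

test_that("tile labeling follows the pixel-fraction rule", {
  img <- matrix(0, 24, 24)
  grid <- tileImage(img, 12)
  mask <- matrix(0L, 24, 24)
  mask[1:12, 1:12] <- 1L                         # tile 1 fully nuclear
  mask[1:5, 13:24] <- 1L                         # tile 2 at 5/12 coverage
  labs <- labelTiles(grid, mask, 0.5)
  expect_equal(labs, c("nuclei", "non_nuclei", "non_nuclei", "non_nuclei"))
  expect_equal(labelTiles(grid, mask, 0.4)[2], "nuclei")
  expect_error(labelTiles(grid, matrix(0, 10, 10)), "shape")
})

test_that("AdaBoost separates linearly separable histograms in one round", {
  H <- rbind(matrix(c(9, 0, 0, 0), 20, 4, byrow = TRUE),
             matrix(c(0, 9, 0, 0), 20, 4, byrow = TRUE))
  y <- rep(c("nuclei", "non_nuclei"), each = 20)
  model <- trainDenoiser(H, y, nRounds = 10)
  expect_equal(model@trainErrors[1], 0)
  pred <- classifyTiles(model, H)
  expect_equal(pred$label, y)
  expect_true(all(pred$score[1:20] > 0))
})

test_that("degenerate training inputs are handled as specified", {
  H <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_error(trainDenoiser(H, rep("nuclei", 4)), "both classes")
  expect_error(trainDenoiser(H, c("nuclei", "nuclei", "non_nuclei",
                                  "non_nuclei"), nRounds = 0), ">= 1")
  # contradictory duplicates: error floor is the minority fraction, no crash
  Hc <- matrix(1, 4, 2)
  yc <- c("nuclei", "nuclei", "non_nuclei", "non_nuclei")
  m <- trainDenoiser(Hc, yc, nRounds = 5)
  expect_equal(m@nRounds, 0L)   # no stump beats chance on identical rows
  pred <- classifyTiles(m, Hc)
  expect_gte(mean(pred$label != yc), 0.5)
})

test_that("boosting drives training error down monotonically on fixed data", {
  withr::with_seed(31, {
    n <- 120
    H <- rbind(matrix(rpois(n * 4 / 2, c(8, 2, 1, 1)), n / 2, 4, byrow = TRUE),
               matrix(rpois(n * 4 / 2, c(2, 7, 2, 1)), n / 2, 4, byrow = TRUE))
    y <- rep(c("nuclei", "non_nuclei"), each = n / 2)
    m <- trainDenoiser(H, y, nRounds = 30)
    expect_true(all(diff(cummin(m@trainErrors)) <= 0))
    expect_lt(utils::tail(m@trainErrors, 1), m@trainErrors[1] + 1e-12)
    # exponential-loss certificate: every kept round had weighted error < 0.5
    expect_true(all(m@alphas > 0))
  })
})

test_that("classification handles empty input, single stumps and mismatches", {
  H <- rbind(matrix(c(9, 0), 5, 2, byrow = TRUE),
             matrix(c(0, 9), 5, 2, byrow = TRUE))
  y <- rep(c("nuclei", "non_nuclei"), each = 5)
  m <- trainDenoiser(H, y, nRounds = 1)
  expect_equal(m@nRounds, 1L)
  expect_equal(classifyTiles(m, H)$label, y)   # equals the stump's rule
  expect_equal(nrow(classifyTiles(m, matrix(numeric(0), 0, 2))), 0)
  expect_error(classifyTiles(m, matrix(1, 2, 5)), "does not match")
})

test_that("background removal blanks exactly the non-nuclei tiles", {
  img <- matrix(seq_len(24 * 24), 24, 24)
  grid <- tileImage(img, 12)
  expect_identical(removeBackground(img, grid, rep("nuclei", 4)), img)
  allGone <- removeBackground(img, grid, rep("non_nuclei", 4))
  expect_true(all(allGone == 0))
  checker <- c("nuclei", "non_nuclei", "non_nuclei", "nuclei")
  out <- removeBackground(img, grid, checker)
  expect_equal(sum(out != img), 2 * 144)       # exactly half the tiled pixels
  # nuclei tiles unchanged value-for-value
  expect_equal(out[1:12, 1:12], img[1:12, 1:12], ignore_attr = TRUE)
  # remainder pixels pass through unchanged
  img2 <- matrix(1, 25, 25)
  g2 <- tileImage(img2, 12)
  out2 <- removeBackground(img2, g2, rep("non_nuclei", 4))
  expect_true(all(out2[25, ] == 1) && all(out2[, 25] == 1))
  expect_error(removeBackground(img, grid, rep("nuclei", 3)), "one label")
})

test_that("leave-one-image-out tile classification exceeds 0.85 accuracy", {
  samples <- generateDataset(
    4, syntheticParams(imageSize = c(256, 256), nNuclei = 8,
                       radiusRange = c(10, 18), background = "mixed"),
    seed = 5)
  cfg <- pipelineConfig(patchSize = 4L, tileSize = 12L, nCodes = 4L)
  prep <- noiseletHE:::.prepareSamples(samples, 4L, cfg$segmenter)
  acc <- vapply(seq_along(samples), function(i) {
    fold <- noiseletHE:::.trainFold(prep[-i], cfg)
    grid <- tileImage(prep[[i]]$hema, cfg$tileSize)
    pred <- classifyTiles(fold$model,
                          encodeTiles(prep[[i]]$hema, grid, fold$book))
    truth <- labelTiles(grid, nucleiMask(samples[[i]]), cfg$overlapThreshold)
    mean(pred$label == truth)
  }, numeric(1))
  expect_gt(mean(acc), 0.85)
})
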