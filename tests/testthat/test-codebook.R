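test_that("patch extraction yields a deterministic row-major grid", {
  reg <- matrix(seq_len(144), 12, 12)
  expect_length(extractPatches(reg, 4), 9)
  expect_error(extractPatches(reg, 8), "divide")
  tiny <- matrix(1:4, 2, 2)
  expect_identical(extractPatches(tiny, 2)[[1]], tiny)
  # first patch is the top-left block, second is one step right
  ps <- extractPatches(reg, 4)
  expect_identical(ps[[1]], reg[1:4, 1:4])
  expect_identical(ps[[2]], reg[1:4, 5:8])
})

test_that("K = 1 codebook is the coordinate-wise median", {
  withr::with_seed(5, {
    X <- matrix(rnorm(400), 50, 8)
    book <- buildCodebook(X, 1, seed = 1, patchSize = 2L)
    expect_equal(as.vector(codewords(book)), apply(X, 2, median))
  })
})

test_that("well-separated clouds are recovered with pure assignments", {
  withr::with_seed(9, {
    A <- matrix(rnorm(400, mean = 0, sd = 0.5), 50, 8)
    B <- matrix(rnorm(400, mean = 30, sd = 0.5), 50, 8)
    X <- rbind(A, B)
    book <- buildCodebook(X, 2, seed = 3)
    code <- assignCode(X, book)
    purity <- max(table(code[1:50])) / 50
    expect_equal(purity, 1)
    expect_equal(length(unique(code)), 2)
    # each centroid lies inside the coordinate range of one cloud
    C <- codewords(book)
    lo <- C[, 1] < 15
    expect_true(all(C[lo, ] > min(A) & C[lo, ] < max(A)))
    expect_true(all(C[!lo, ] > min(B) & C[!lo, ] < max(B)))
  })
})

test_that("k-means objective is non-increasing and runs are seed-deterministic", {
  withr::with_seed(13, {
    X <- matrix(rnorm(1600), 200, 8)
    b1 <- buildCodebook(X, 4, seed = 7)
    b2 <- buildCodebook(X, 4, seed = 7)
    expect_identical(codewords(b1), codewords(b2))
    expect_true(all(diff(b1@objective) <= 1e-9))
  })
})

test_that("identical features with K = 2 do not crash (empty-cluster rule)", {
  X <- matrix(1, 10, 8)
  book <- buildCodebook(X, 2, seed = 1)
  code <- assignCode(X, book)
  expect_equal(length(unique(code)), 1)  # one populated cluster
})

test_that("assignment matches an exhaustive L1 search and breaks ties low", {
  withr::with_seed(17, {
    book <- buildCodebook(matrix(rnorm(800), 100, 8), 5, seed = 2)
    C <- codewords(book)
    X <- matrix(rnorm(800), 100, 8)
    oracle <- apply(X, 1, function(x) {
      d <- apply(C, 1, function(cc) sum(abs(x - cc)))
      which(d == min(d))[1]
    })
    expect_equal(assignCode(X, book), unname(oracle))
    # feature equal to a centroid maps to it (quantization idempotence)
    expect_equal(assignCode(C, book), seq_len(nrow(C)))
    # exact tie between the first two centroids resolves to the lower index
    tie <- matrix(c(0, 0), 1, 2)
    tb <- new("NoiseletCodebook", centroids = rbind(c(-1, 0), c(1, 0)),
              patchSize = 1L, distance = "cityblock", seed = 1L,
              objective = numeric(0))
    expect_equal(assignCode(tie, tb), 1L)
  })
  expect_error(assignCode(matrix(1, 1, 3),
                          buildCodebook(matrix(rnorm(80), 10, 8), 2,
                                        seed = 1)),
               "dimension")
})

test_that("K outside 1..N and empty feature sets are rejected", {
  X <- matrix(rnorm(40), 5, 8)
  expect_error(buildCodebook(X, 6, seed = 1), "K must satisfy")
  expect_error(buildCodebook(X, 0, seed = 1), "K must satisfy")
  expect_error(buildCodebook(matrix(numeric(0), 0, 8), 1, seed = 1),
               "non-empty")
})

test_that("two-texture synthetic data yields >= 90% single-class code purity at K = 2", {
  s <- generateSample(syntheticParams(imageSize = c(256, 256), nNuclei = 16,
                                      radiusRange = c(12, 20),
                                      background = "fibrous_stroma",
                                      seed = 5))
  M <- estimateStainMatrix(sampleImage(s))
  hema <- separateHematoxylin(sampleImage(s), M)
  feats <- noiseletHE:::.patchFeatureMatrix(hema, noiseletBasis(4))
  patchLabels <- labelTiles(tileImage(hema, 4), nucleiMask(s), 0.5)
  book <- buildCodebook(feats, 2, seed = 1)
  tab <- table(assignCode(feats, book), patchLabels)
  purity <- apply(tab, 1, max) / rowSums(tab)
  expect_true(all(purity >= 0.9))
})
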