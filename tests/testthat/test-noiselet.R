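test_that("basis matches the hand-evaluated recursion and rejects bad sizes", {
  expect_equal(basisMatrix(noiseletBasis(1)), matrix(1 + 0i, 1, 1))
  expect_equal(basisMatrix(noiseletBasis(2)), handNoiselet2())
  expect_error(noiseletBasis(3), "power of 2")
  expect_error(noiseletBasis(0), "power of 2")
  expect_error(noiseletBasis(6), "power of 2")
})

test_that("basis is unitary with flat entry magnitudes for all dyadic sizes", {
  for (m in c(1, 2, 4, 8, 16)) {
    B <- basisMatrix(noiseletBasis(m))
    expect_lt(max(abs(B %*% Conj(t(B)) - diag(m))), 1e-10)
    expect_lt(max(abs(Mod(B) - 1 / sqrt(m))), 1e-10)
  }
})

test_that("1D transform reproduces hand-computed coefficients", {
  b2 <- noiseletBasis(2)
  # constant signal stays at phase 0
  expect_equal(noiseletTransform1d(c(1, 1), b2),
               as.vector(handNoiselet2() %*% c(1, 1)))
  expect_equal(noiseletTransform1d(c(1, 1), b2), c(1 + 0i, 1 + 0i))
  # alternating signal is purely imaginary
  expect_equal(noiseletTransform1d(c(1, -1), b2), c(0 - 1i, 0 + 1i))
  expect_error(noiseletTransform1d(c(1, 2, 3), b2), "does not match")
})

test_that("deltas have flat coefficient spectra (magnitude 1/sqrt(m))", {
  for (m in c(2, 4, 8, 16)) {
    b <- noiseletBasis(m)
    for (pos in c(1, m %/% 2, m)) {
      delta <- rep(0, m); delta[pos] <- 1
      expect_lt(max(abs(Mod(noiseletTransform1d(delta, b)) - 1 / sqrt(m))),
                1e-10)
    }
  }
})

test_that("low and high frequencies separate by a 90 degree phase", {
  for (m in c(2, 4, 8)) {
    b <- noiseletBasis(m)
    cc <- noiseletTransform1d(rep(1, m), b)
    ca <- noiseletTransform1d(rep(c(1, -1), m / 2), b)
    dphi <- abs(Arg(cc[which.max(Mod(cc))]) - Arg(ca[which.max(Mod(ca))]))
    expect_lt(abs(dphi - pi / 2), 1e-6)
  }
})

test_that("transforms are linear and invert exactly", {
  withr::with_seed(42, {
    b <- noiseletBasis(8)
    x <- rnorm(8); y <- rnorm(8)
    lhs <- noiseletTransform1d(2.5 * x - 1.3 * y, b)
    rhs <- 2.5 * noiseletTransform1d(x, b) - 1.3 * noiseletTransform1d(y, b)
    expect_lt(max(Mod(lhs - rhs)), 1e-10)
    expect_lt(max(Mod(inverseNoiselet1d(noiseletTransform1d(x, b), b) - x)),
              1e-10)

    P <- matrix(rnorm(64), 8, 8)
    C <- noiseletTransform2d(P, b)
    expect_lt(max(Mod(inverseNoiselet2d(C, b) - P)), 1e-10)
    # Parseval under the unitary normalization
    expect_lt(abs(sum(Mod(C)^2) - sum(P^2)), 1e-8)
    # two-sided identity: transform of an inverse recovers the coefficients
    Cr <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
    expect_lt(max(Mod(noiseletTransform2d(inverseNoiselet2d(Cr, b), b) - Cr)),
              1e-10)
  })
})

test_that("2D transform of a zero or constant patch behaves as derived", {
  b2 <- noiseletBasis(2)
  expect_equal(noiseletTransform2d(matrix(0, 2, 2), b2), matrix(0i, 2, 2))
  # constant 2x2 patch of ones: separable application of the 1D constant case
  C <- noiseletTransform2d(matrix(1, 2, 2), b2)
  oracle <- handNoiselet2() %*% matrix(1, 2, 2) %*% t(handNoiselet2())
  expect_equal(C, oracle)
  expect_lt(abs(sum(Mod(C)^2) - 4), 1e-10)   # energy 4 preserved
  expect_error(noiseletTransform2d(matrix(1, 2, 3), b2), "2x2")
})

test_that("patch features concatenate real then imaginary parts, length 2 m^2", {
  b2 <- noiseletBasis(2); b4 <- noiseletBasis(4)
  expect_length(patchFeatures(matrix(rnorm(4), 2, 2), b2), 8)
  expect_length(patchFeatures(matrix(rnorm(16), 4, 4), b4), 32)
  expect_equal(patchFeatures(matrix(0, 4, 4), b4), rep(0, 32))
  # layout: row-major real block then row-major imaginary block
  P <- matrix(rnorm(4), 2, 2)
  C <- noiseletTransform2d(P, b2)
  expect_equal(patchFeatures(P, b2), c(Re(t(C)), Im(t(C))))
})

test_that("vectorized patch features agree with the per-patch path", {
  withr::with_seed(3, {
    b <- noiseletBasis(4)
    reg <- matrix(rnorm(12 * 16), 12, 16)
    F <- noiseletHE:::.patchFeatureMatrix(reg, b)
    oracle <- t(vapply(extractPatches(reg, 4), patchFeatures, numeric(32),
                       basis = b))
    expect_equal(F, oracle, tolerance = 1e-12)
  })
})
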