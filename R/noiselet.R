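#' Build the discrete noiselet basis
#'
#' Constructs the m x m complex noiselet matrix from the Haar-Walsh
#' recursion. The generation starts from the indicator of [0,1) and at
#' each doubling maps a function f to the pair
#' (1-i) f(2x) + (1+i) f(2x-1) and (1+i) f(2x) + (1-i) f(2x-1),
#' so low- and high-frequency content ends up separated by a 90 degree
#' phase in the complex plane. Row r of the result is function number
#' m + r of the family, sampled on the m dyadic subintervals of [0,1),
#' scaled so the matrix is unitary (all entries have magnitude
#' 1/sqrt(m) and Parseval's identity holds).
#'
#' @param m basis size; must be a power of 2
#' @return a [NoiseletBasis-class] object
#' @examples
#' b <- noiseletBasis(4)
#' Mod(basisMatrix(b))   # flat magnitude 1/2
#' @export
noiseletBasis <- function(m) {
  if (!.isPow2(m))
    stop("noiselet basis size must be a power of 2, got ", m, call. = FALSE)
  m <- as.integer(m)
  V <- matrix(1 + 0i, 1L, 1L)
  while (ncol(V) < m) {
    k <- nrow(V)
    W <- matrix(0i, 2L * k, 2L * k)
    W[seq(1L, 2L * k, by = 2L), ] <- cbind((1 - 1i) * V, (1 + 1i) * V)
    W[seq(2L, 2L * k, by = 2L), ] <- cbind((1 + 1i) * V, (1 - 1i) * V)
    V <- W
  }
  new("NoiseletBasis", size = m, matrix = V / m)
}

#' Forward 1D noiselet transform
#'
#' Projects a length-m signal onto the noiselet basis (matrix product
#' with the unitary basis). Constant signals map to phase-0 coefficients
#' while maximally alternating signals map to purely imaginary ones.
#'
#' @param signal real or complex vector of length `basisSize(basis)`
#' @param basis a [NoiseletBasis-class]
#' @return complex coefficient vector of the same length
#' @export
noiseletTransform1d <- function(signal, basis) {
  stopifnot(is(basis, "NoiseletBasis"))
  if (length(signal) != basis@size)
    stop("signal length ", length(signal), " does not match basis size ",
         basis@size, call. = FALSE)
  as.vector(basis@matrix %*% signal)
}

#' Inverse 1D noiselet transform
#' @param coeffs complex coefficient vector
#' @inheritParams noiseletTransform1d
#' @return reconstructed signal (complex; take Re() for real inputs)
#' @export
inverseNoiselet1d <- function(coeffs, basis) {
  stopifnot(is(basis, "NoiseletBasis"))
  if (length(coeffs) != basis@size)
    stop("coefficient length does not match basis size", call. = FALSE)
  as.vector(Conj(t(basis@matrix)) %*% coeffs)
}

#' Forward 2D noiselet transform of a square patch
#'
#' Separable transform: the basis is applied along rows, then along
#' columns (C = N P N^T). Unitary in 2D, so energy is preserved.
#'
#' @param patch m x m numeric or complex matrix
#' @inheritParams noiseletTransform1d
#' @return m x m complex coefficient matrix
#' @export
noiseletTransform2d <- function(patch, basis) {
  stopifnot(is(basis, "NoiseletBasis"))
  m <- basis@size
  if (!is.matrix(patch) || nrow(patch) != m || ncol(patch) != m)
    stop("patch must be ", m, "x", m, " to match the basis", call. = FALSE)
  basis@matrix %*% patch %*% t(basis@matrix)
}

#' Inverse 2D noiselet transform
#' @param coeffs m x m complex coefficient matrix
#' @inheritParams noiseletTransform1d
#' @return reconstructed m x m patch (complex; Re() for real patches)
#' @export
inverseNoiselet2d <- function(coeffs, basis) {
  stopifnot(is(basis, "NoiseletBasis"))
  m <- basis@size
  if (!is.matrix(coeffs) || nrow(coeffs) != m || ncol(coeffs) != m)
    stop("coefficients must be ", m, "x", m, " to match the basis", call. = FALSE)
  Conj(t(basis@matrix)) %*% coeffs %*% Conj(basis@matrix)
}

#' Patch feature vector in noiselet space
#'
#' Transforms an m x m patch and flattens the complex coefficients into
#' a real feature vector: real parts first, then imaginary parts, both
#' in row-major order. Length 2 m^2 (8 features for 2 x 2 patches).
#'
#' @inheritParams noiseletTransform2d
#' @return numeric vector of length `2 * basisSize(basis)^2`
#' @export
patchFeatures <- function(patch, basis) {
  C <- noiseletTransform2d(patch, basis)
  rm <- as.vector(t(C))       # row-major flattening
  c(Re(rm), Im(rm))
}

#' Noiselet features of every patch of a region
#'
#' Vectorized [patchFeatures()] over all non-overlapping m x m patches
#' of a region, in row-major patch-grid order (matching
#' [extractPatches()]).
#'
#' @param region h x w numeric matrix; the patch size must divide both
#'   dimensions
#' @param basis a [NoiseletBasis-class], or a patch size (power of 2)
#'   from which one is built
#' @return P x 2 m^2 numeric matrix, one feature row per patch
#' @export
patchFeatureMatrix <- function(region, basis) {
  if (is.numeric(basis)) basis <- noiseletBasis(basis)
  .patchFeatureMatrix(region, basis)
}

# Vectorized features for all non-overlapping m x m patches of a region.
# Returns a P x 2m^2 matrix; patch order is row-major over the patch grid
# (top-left to bottom-right), matching extractPatches().
.patchFeatureMatrix <- function(region, basis) {
  m <- basis@size
  h <- nrow(region); w <- ncol(region)
  if (h %% m != 0L || w %% m != 0L)
    stop("patch size ", m, " must divide region dimensions ", h, "x", w,
         call. = FALSE)
  gr <- h %/% m; gc <- w %/% m
  A <- array(region, c(m, gr, m, gc))
  # columns = column-major vec of each patch, patches in row-major grid order
  P <- matrix(aperm(A, c(1L, 3L, 4L, 2L)), nrow = m * m)
  K2 <- kronecker(basis@matrix, basis@matrix)   # vec(N P N^T) = (N x N) vec(P)
  F <- K2 %*% P
  rowmajor <- as.vector(t(matrix(seq_len(m * m), nrow = m)))
  F <- F[rowmajor, , drop = FALSE]
  t(rbind(Re(F), Im(F)))
}
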