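#' Default H&E stain matrix
#'
#' Standard optical-density vectors for hematoxylin (0.65, 0.70, 0.29)
#' and eosin (0.07, 0.99, 0.11), unit-normalized, as columns of a 3 x 2
#' matrix. Used by the synthetic generator and as a fallback fixed
#' matrix when per-image estimation is not wanted.
#'
#' @return 3 x 2 matrix with unit-norm columns (hematoxylin, eosin)
#' @export
defaultStainMatrix <- function() {
  M <- cbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin       = c(0.07, 0.99, 0.11))
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' Convert RGB intensities to optical density
#'
#' Beer-Lambert: od = -log((I + eps) / I0), per channel, with a small
#' eps guarding log(0). Stain concentrations mix linearly in OD space.
#'
#' @param image H x W x 3 array of intensities in [0, background]
#' @param background background (white) intensity per channel, default 255
#' @param eps small positive constant inside the log
#' @return H x W x 3 array of optical densities (>= 0 below background)
#' @export
rgbToOD <- function(image, background = 255, eps = 1e-6) {
  if (any(background <= 0))
    stop("background intensity must be positive", call. = FALSE)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  bg <- rep(background, length.out = 3L)
  od <- image
  # eps in both numerator and denominator: exact 0 at background, >= 0 below
  for (ch in 1:3) od[, , ch] <- -log((image[, , ch] + eps) / (bg[ch] + eps))
  od
}

#' Estimate the H&E stain matrix (Macenko)
#'
#' Foreground OD pixels (Euclidean OD norm above `odThreshold`) are
#' projected on the plane of their top-2 singular directions; the two
#' stain vectors are the extreme-angle directions at the `alphaPercentile`
#' and 1 - `alphaPercentile` angle quantiles, mapped back to 3D,
#' clamped non-negative and unit-normalized. The hematoxylin column is
#' the one with the larger blue-channel OD component.
#'
#' @inheritParams rgbToOD
#' @param alphaPercentile robust angle percentile (default 0.01)
#' @param odThreshold minimum OD norm for a pixel to count as tissue
#' @return 3 x 2 stain matrix, columns (hematoxylin, eosin)
#' @export
estimateStainMatrix <- function(image, alphaPercentile = 0.01,
                                odThreshold = 0.15, background = 255) {
  od <- rgbToOD(image, background)
  X <- matrix(od, ncol = 3L)          # pixels x channels
  keep <- sqrt(rowSums(X^2)) > odThreshold
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2L)
    stop("degenerate input: fewer than 2 tissue pixels above the OD threshold",
         call. = FALSE)
  sv <- svd(X, nu = 0, nv = 2)
  if (sv$d[2] < 1e-8 * sv$d[1] || sv$d[2] < 1e-10)
    stop("degenerate input: foreground OD has no chromatic plane ",
         "(achromatic or single-stain image)", call. = FALSE)
  V <- sv$v                            # 3 x 2 plane basis
  # orient the basis so projections have a consistent sign
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  proj <- X %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alphaPercentile, 1 - alphaPercentile),
                       names = FALSE, type = 7)
  dir <- function(a) {
    v <- V %*% c(cos(a), sin(a))
    v <- pmax(v, 0)
    n <- sqrt(sum(v^2))
    if (n < 1e-8)
      stop("degenerate input: extreme stain direction collapsed to zero",
           call. = FALSE)
    v / n
  }
  v1 <- dir(q[1]); v2 <- dir(q[2])
  if (v1[3] >= v2[3]) M <- cbind(v1, v2) else M <- cbind(v2, v1)
  dimnames(M) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  M
}

#' Separate the hematoxylin concentration map
#'
#' Solves od = stains %*% c per pixel by non-negative least squares
#' (closed form for two stains: the unconstrained solution, or the best
#' single-stain projection clamped at zero when a component goes
#' negative) and returns the hematoxylin component as an image.
#'
#' @inheritParams rgbToOD
#' @param stains 3 x 2 stain matrix with unit-norm non-negative columns
#' @return H x W numeric matrix of non-negative hematoxylin concentrations
#' @export
separateHematoxylin <- function(image, stains, background = 255) {
  if (!is.matrix(stains) || !all(dim(stains) == c(3L, 2L)))
    stop("stains must be a 3 x 2 matrix", call. = FALSE)
  if (max(abs(colSums(stains^2) - 1)) > 1e-6 || any(stains < -1e-9))
    stop("stain columns must be unit-norm and non-negative", call. = FALSE)
  od <- rgbToOD(image, background)
  h <- dim(od)[1]; w <- dim(od)[2]
  X <- t(matrix(od, ncol = 3L))       # 3 x P
  G <- crossprod(stains)              # 2 x 2
  C <- solve(G, crossprod(stains, X)) # unconstrained LS, 2 x P
  neg <- C[1, ] < 0 | C[2, ] < 0
  if (any(neg)) {
    Xn <- X[, neg, drop = FALSE]
    c1 <- pmax(0, colSums(stains[, 1] * Xn))   # single-stain fits
    c2 <- pmax(0, colSums(stains[, 2] * Xn))
    r1 <- colSums((Xn - outer(stains[, 1], c1))^2)
    r2 <- colSums((Xn - outer(stains[, 2], c2))^2)
    useH <- r1 <= r2
    C[1, neg] <- ifelse(useH, c1, 0)
    C[2, neg] <- ifelse(useH, 0, c2)
  }
  matrix(pmax(C[1, ], 0), h, w)
}
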