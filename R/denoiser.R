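#' Divide an image into non-overlapping tiles
#'
#' Row-major grid of t x t tiles anchored at the top-left corner.
#' Remainder pixels (image dimension mod t) are excluded from the grid
#' and recorded; they are passed through unchanged by
#' [removeBackground()].
#'
#' @param image h x w matrix (or H x W x 3 array; only the spatial
#'   dimensions are used)
#' @param tileSize tile side t
#' @return a `tileGrid` list: tileSize, gridRows, gridCols, nTiles,
#'   imageShape, remainder (pixels dropped per axis)
#' @export
tileImage <- function(image, tileSize) {
  t <- .assertScalarInt(tileSize, "tileSize")
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (t < 1L || t > min(h, w))
    stop("tile size ", t, " exceeds image dimensions ", h, "x", w,
         call. = FALSE)
  gr <- h %/% t; gc <- w %/% t
  structure(list(tileSize = t, gridRows = gr, gridCols = gc,
                 nTiles = gr * gc, imageShape = c(h, w),
                 remainder = c(h %% t, w %% t)),
            class = "tileGrid")
}

# rows/cols spanned by tile index i (row-major) of a grid
.tileExtent <- function(grid, i) {
  t <- grid$tileSize
  r <- (i - 1L) %/% grid$gridCols
  c <- (i - 1L) %% grid$gridCols
  list(rows = (r * t + 1L):((r + 1L) * t),
       cols = (c * t + 1L):((c + 1L) * t))
}

#' Encode one tile as a codeword histogram
#'
#' The tile is split into patches of the codebook's patch size, each
#' patch's noiselet features are quantized against the codebook, and
#' occurrences are counted. Counts always sum to (t/m)^2.
#'
#' @param tile t x t numeric matrix
#' @param book a [NoiseletCodebook-class]
#' @param basis optional precomputed [NoiseletBasis-class] of matching size
#' @return integer vector of K codeword counts
#' @export
encodeTile <- function(tile, book, basis = NULL) {
  stopifnot(is(book, "NoiseletCodebook"))
  m <- book@patchSize
  t <- nrow(tile)
  if (!is.matrix(tile) || ncol(tile) != t || t %% m != 0L)
    stop("tile must be square with side divisible by the patch size ", m,
         call. = FALSE)
  basis <- basis %||% noiseletBasis(m)
  feats <- .patchFeatureMatrix(tile, basis)
  tabulate(assignCode(feats, book), nbins = nrow(book@centroids))
}

#' Encode every tile of an image
#'
#' Vectorized version of [encodeTile()] over a [tileImage()] grid:
#' computes all patch features of the tiled area at once and aggregates
#' codeword counts per tile.
#'
#' @param image h x w numeric matrix (typically a hematoxylin map)
#' @param grid a `tileGrid` from [tileImage()]
#' @inheritParams encodeTile
#' @return nTiles x K integer matrix of histograms (row-major tile order)
#' @export
encodeTiles <- function(image, grid, book, basis = NULL) {
  stopifnot(inherits(grid, "tileGrid"), is(book, "NoiseletCodebook"))
  m <- book@patchSize
  t <- grid$tileSize
  if (t %% m != 0L)
    stop("patch size ", m, " must divide tile size ", t, call. = FALSE)
  basis <- basis %||% noiseletBasis(m)
  crop <- image[seq_len(grid$gridRows * t), seq_len(grid$gridCols * t),
                drop = FALSE]
  feats <- .patchFeatureMatrix(crop, basis)
  codes <- assignCode(feats, book)
  ppt <- t %/% m                                   # patches per tile side
  pgc <- grid$gridCols * ppt                       # patch-grid columns
  p <- seq_along(codes) - 1L
  pi <- p %/% pgc; pj <- p %% pgc                  # 0-based patch coords
  tileIdx <- (pi %/% ppt) * grid$gridCols + (pj %/% ppt) + 1L
  K <- nrow(book@centroids)
  counts <- matrix(0L, grid$nTiles, K)
  tab <- tabulate(tileIdx + grid$nTiles * (codes - 1L), grid$nTiles * K)
  counts[] <- tab
  counts
}

#' Label tiles from a ground-truth nuclei mask
#'
#' A tile is labeled `"nuclei"` when at least `overlapThreshold` of its
#' pixels fall inside the mask, `"non_nuclei"` otherwise.
#'
#' @param grid a `tileGrid`
#' @param mask binary (or instance) nuclei mask matching the grid's image
#' @param overlapThreshold pixel-fraction threshold, default 0.5
#' @return character vector of tile labels in row-major tile order
#' @export
labelTiles <- function(grid, mask, overlapThreshold = 0.5) {
  stopifnot(inherits(grid, "tileGrid"))
  if (!all(dim(mask)[1:2] == grid$imageShape))
    stop("mask shape does not match the tiled image", call. = FALSE)
  t <- grid$tileSize
  bin <- (mask > 0) + 0
  crop <- bin[seq_len(grid$gridRows * t), seq_len(grid$gridCols * t),
              drop = FALSE]
  A <- array(crop, c(t, grid$gridRows, t, grid$gridCols))
  frac <- t(apply(A, c(2L, 4L), sum)) / (t * t)    # gridCols x gridRows
  ifelse(as.vector(frac) >= overlapThreshold, "nuclei", "non_nuclei")
}

#' Train the AdaBoost tile denoiser
#'
#' Discrete AdaBoost over depth-1 decision stumps on the histogram bins.
#' Each round picks the weighted-error-minimizing (bin, threshold,
#' polarity) stump; training halts early if no stump beats 0.5 weighted
#' error. Deterministic for fixed inputs.
#'
#' @param histograms N x K matrix of tile codeword counts
#' @param labels character vector, `"nuclei"` / `"non_nuclei"`
#' @param nRounds maximum number of stumps (default 50)
#' @param seed RNG seed recorded in the model (training is deterministic)
#' @param patchSize,tileSize configuration metadata recorded in the model
#' @return a [TileDenoiser-class]
#' @export
trainDenoiser <- function(histograms, labels, nRounds = 50L, seed = 1L,
                          patchSize = NA_integer_, tileSize = NA_integer_) {
  if (!is.matrix(histograms)) histograms <- as.matrix(histograms)
  N <- nrow(histograms); K <- ncol(histograms)
  if (length(labels) != N)
    stop("one label per histogram required", call. = FALSE)
  y <- ifelse(labels == "nuclei", 1, -1)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to train the denoiser", call. = FALSE)
  nRounds <- .assertScalarInt(nRounds, "nRounds")
  if (nRounds < 1L) stop("nRounds must be >= 1", call. = FALSE)

  ord <- lapply(seq_len(K), function(j) order(histograms[, j]))
  w <- rep(1 / N, N)
  featureIdx <- integer(0); thresholds <- numeric(0)
  polarity <- numeric(0); alphas <- numeric(0); trainErrors <- numeric(0)
  score <- numeric(N)

  for (round in seq_len(nRounds)) {
    best <- list(err = Inf)
    for (j in seq_len(K)) {
      o <- ord[[j]]
      x <- histograms[o, j]
      wy <- w[o]
      plusLeft <- cumsum(wy * (y[o] > 0))     # weight of +1 in x <= cut
      minusLeft <- cumsum(wy * (y[o] < 0))
      Wminus <- minusLeft[N]
      # candidate cuts between distinct values, plus the two extremes
      cuts <- c(0L, which(diff(x) > 0), N)
      for (i in cuts) {
        pl <- if (i == 0L) 0 else plusLeft[i]
        ml <- if (i == 0L) 0 else minusLeft[i]
        # polarity +1: predict nuclei when value > threshold
        errPos <- pl + (Wminus - ml)
        thr <- if (i == 0L) x[1] - 1 else if (i == N) x[N] else
          (x[i] + x[i + 1]) / 2
        for (pol in c(1, -1)) {
          err <- if (pol > 0) errPos else 1 - errPos
          if (err < best$err - 1e-12) {
            best <- list(err = err, j = j, thr = thr, pol = pol)
          }
        }
      }
    }
    if (best$err >= 0.5 - 1e-12) break        # no useful weak learner left
    err <- max(best$err, 1e-12)
    alpha <- 0.5 * log((1 - err) / err)
    pred <- best$pol * ifelse(histograms[, best$j] > best$thr, 1, -1)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    featureIdx <- c(featureIdx, best$j)
    thresholds <- c(thresholds, best$thr)
    polarity <- c(polarity, best$pol)
    alphas <- c(alphas, alpha)
    score <- score + alpha * pred
    trainErrors <- c(trainErrors, mean(ifelse(score > 0, 1, -1) != y))
    if (utils::tail(trainErrors, 1) == 0) break
  }
  new("TileDenoiser", featureIdx = as.integer(featureIdx),
      thresholds = thresholds, polarity = polarity, alphas = alphas,
      nRounds = length(alphas), patchSize = as.integer(patchSize),
      tileSize = as.integer(tileSize), nCodes = as.integer(K),
      trainErrors = trainErrors, seed = as.integer(seed))
}

#' Classify tiles as nuclei or non-nuclei
#'
#' Weighted stump vote; the score is the signed margin, positive for
#' nuclei.
#'
#' @param model a [TileDenoiser-class]
#' @param histograms N x K matrix of tile codeword counts
#' @return data.frame with columns `label` and `score`
#' @export
classifyTiles <- function(model, histograms) {
  stopifnot(is(model, "TileDenoiser"))
  if (!is.matrix(histograms)) histograms <- matrix(histograms, ncol = model@nCodes)
  if (nrow(histograms) == 0L)
    return(data.frame(label = character(0), score = numeric(0)))
  if (ncol(histograms) != model@nCodes)
    stop("histogram dimension ", ncol(histograms),
         " does not match the model's ", model@nCodes, " codes", call. = FALSE)
  score <- numeric(nrow(histograms))
  for (r in seq_len(model@nRounds)) {
    pred <- model@polarity[r] *
      ifelse(histograms[, model@featureIdx[r]] > model@thresholds[r], 1, -1)
    score <- score + model@alphas[r] * pred
  }
  data.frame(label = ifelse(score > 0, "nuclei", "non_nuclei"),
             score = score)
}

#' Blank out non-nuclei tiles
#'
#' Pixels of tiles labeled `"non_nuclei"` are set to `fillValue`
#' (default: 0 for single-channel maps, the background white for RGB
#' arrays); nuclei tiles and the cropped remainder margin are returned
#' bit-identical to the input.
#'
#' @param image h x w matrix or H x W x 3 array
#' @param grid the `tileGrid` the labels refer to
#' @param labels character tile labels from [classifyTiles()] or
#'   [labelTiles()]
#' @param fillValue replacement value for removed tiles
#' @return image of the same shape with non-nuclei tiles blanked
#' @export
removeBackground <- function(image, grid, labels, fillValue = NULL) {
  stopifnot(inherits(grid, "tileGrid"))
  if (length(labels) != grid$nTiles)
    stop("need one label per tile (", grid$nTiles, " tiles, ",
         length(labels), " labels)", call. = FALSE)
  if (!all(dim(image)[1:2] == grid$imageShape))
    stop("image shape does not match the grid", call. = FALSE)
  rgb <- length(dim(image)) == 3L
  fillValue <- fillValue %||% if (rgb) 255 else 0
  out <- image
  for (i in which(labels == "non_nuclei")) {
    ext <- .tileExtent(grid, i)
    if (rgb) out[ext$rows, ext$cols, ] <- fillValue
    else out[ext$rows, ext$cols] <- fillValue
  }
  out
}
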