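# N x K matrix of city-block distances between feature rows and centroids
.l1Distances <- function(features, centroids) {
  K <- nrow(centroids)
  D <- matrix(0, nrow(features), K)
  for (k in seq_len(K))
    D[, k] <- rowSums(abs(sweep(features, 2, centroids[k, ], "-")))
  D
}

#' Split a region into non-overlapping patches
#'
#' Row-major grid (top-left to bottom-right) of m x m patches. The patch
#' size must divide both region dimensions.
#'
#' @param region h x w numeric matrix
#' @param patchSize patch side m
#' @return list of m x m matrices, length (h/m) * (w/m)
#' @export
extractPatches <- function(region, patchSize) {
  m <- .assertScalarInt(patchSize, "patchSize")
  h <- nrow(region); w <- ncol(region)
  if (m < 1L || h %% m != 0L || w %% m != 0L)
    stop("patch size ", m, " must divide the region dimensions ",
         h, "x", w, call. = FALSE)
  gr <- h %/% m; gc <- w %/% m
  out <- vector("list", gr * gc)
  p <- 0L
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    p <- p + 1L
    out[[p]] <- region[((i - 1L) * m + 1L):(i * m),
                       ((j - 1L) * m + 1L):(j * m), drop = FALSE]
  }
  out
}

#' Build the noiselet code-book by city-block k-means
#'
#' k-means with L1 assignment and coordinate-wise median centroid
#' update (the update consistent with the L1 objective, which is then
#' non-increasing across iterations). Initialization is k-means++-style
#' seeding with L1 distances under a fixed seed; empty clusters are
#' re-seeded from the point farthest from its assigned centroid.
#'
#' @param features N x D numeric matrix of patch features
#' @param K number of codes (1 <= K <= N)
#' @param seed RNG seed (initialization only; the rest is deterministic)
#' @param maxIter iteration cap; stops earlier at an assignment fixpoint
#' @param nstart independent restarts; the run with the lowest final L1
#'   objective is kept (k-means is sensitive to initialization)
#' @param patchSize patch side recorded in the codebook (inferred from D
#'   when omitted: D = 2 m^2)
#' @return a [NoiseletCodebook-class]; the per-iteration objective trace
#'   is available in the `objective` slot
#' @export
buildCodebook <- function(features, K, seed = 1L, maxIter = 100L,
                          nstart = 5L, patchSize = NULL) {
  if (!is.matrix(features) || nrow(features) == 0L)
    stop("features must be a non-empty N x D matrix", call. = FALSE)
  K <- .assertScalarInt(K, "K")
  N <- nrow(features)
  if (K < 1L || K > N)
    stop("K must satisfy 1 <= K <= N (K = ", K, ", N = ", N, ")",
         call. = FALSE)
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                      max(1L, as.integer(nstart))))
  best <- NULL
  for (s in seeds) {
    cand <- .buildCodebookOnce(features, K, s, maxIter, patchSize)
    if (is.null(best) ||
        utils::tail(cand@objective, 1) < utils::tail(best@objective, 1))
      best <- cand
  }
  best@seed <- as.integer(seed)
  best
}

.buildCodebookOnce <- function(features, K, seed, maxIter, patchSize) {
  N <- nrow(features); D <- ncol(features)
  if (is.null(patchSize)) {
    m <- sqrt(D / 2)
    if (m != as.integer(m))
      stop("cannot infer patchSize from feature dimension ", D, call. = FALSE)
    patchSize <- as.integer(m)
  }
  centroids <- .withSeed(seed, {
    # k-means++ style seeding under L1
    idx <- sample.int(N, 1L)
    C <- features[idx, , drop = FALSE]
    dmin <- rowSums(abs(sweep(features, 2, C[1L, ], "-")))
    while (nrow(C) < K) {
      if (sum(dmin) <= 0) {          # all remaining points coincide
        cand <- sample.int(N, 1L)
      } else {
        cand <- sample.int(N, 1L, prob = dmin / sum(dmin))
      }
      C <- rbind(C, features[cand, , drop = FALSE])
      dmin <- pmin(dmin, rowSums(abs(sweep(features, 2, features[cand, ], "-"))))
    }
    C
  })
  assign <- rep(0L, N)
  objective <- numeric(0)
  for (iter in seq_len(max(1L, as.integer(maxIter)))) {
    Dm <- .l1Distances(features, centroids)
    newAssign <- max.col(-Dm, ties.method = "first")
    objective <- c(objective, sum(Dm[cbind(seq_len(N), newAssign)]))
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (k in seq_len(K)) {
      members <- which(assign == k)
      if (length(members) == 0L) {
        # empty cluster: re-seed from the point farthest from its centroid
        far <- which.max(Dm[cbind(seq_len(N), assign)])
        centroids[k, ] <- features[far, ]
      } else {
        centroids[k, ] <- apply(features[members, , drop = FALSE], 2,
                                stats::median)
      }
    }
  }
  new("NoiseletCodebook", centroids = centroids,
      patchSize = as.integer(patchSize), distance = "cityblock",
      seed = as.integer(seed), objective = objective)
}

#' Quantize features to code words
#'
#' Returns, for each feature row, the 1-based index of the city-block
#' nearest centroid; ties break to the lowest index.
#'
#' @param features D-vector or N x D matrix of features
#' @param book a [NoiseletCodebook-class]
#' @return integer vector of code indices in 1..K
#' @export
assignCode <- function(features, book) {
  stopifnot(is(book, "NoiseletCodebook"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != ncol(book@centroids))
    stop("feature dimension ", ncol(features), " does not match codebook ",
         "dimension ", ncol(book@centroids), call. = FALSE)
  Dm <- .l1Distances(features, book@centroids)
  max.col(-Dm, ties.method = "first")
}
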