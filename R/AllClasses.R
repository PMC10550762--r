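#' @import methods
NULL

#' Noiselet basis of dyadic size
#'
#' A unitary complex matrix whose rows are the discrete noiselet functions
#' built from the Haar-Walsh recursion, sampled on the dyadic subintervals
#' of [0,1). Every entry has magnitude 1/sqrt(m), so coefficients of
#' localized signals spread flatly across the spectrum, and low and high
#' frequencies land in complex-plane quadrants 90 degrees apart.
#'
#' @slot size basis size m, a power of 2
#' @slot matrix m x m complex unitary matrix
#' @export
setClass("NoiseletBasis",
  representation(size = "integer", matrix = "matrix"),
  validity = function(object) {
    m <- object@size
    if (!.isPow2(m)) return("size must be a power of 2")
    B <- object@matrix
    if (!is.complex(B) || !all(dim(B) == m)) return("matrix must be m x m complex")
    if (max(abs(B %*% Conj(t(B)) - diag(m))) > 1e-10) return("matrix is not unitary")
    if (max(abs(Mod(B) - 1 / sqrt(m))) > 1e-10)
      return("entries must all have magnitude 1/sqrt(m)")
    TRUE
  }
)

#' Noiselet code-book
#'
#' K centroids in patch-feature space (concatenated real and imaginary
#' noiselet coefficients of an m x m patch), learned by k-means under
#' city-block (L1) distance with coordinate-wise median updates.
#'
#' @slot centroids K x D numeric matrix, D = 2 m^2
#' @slot patchSize patch side m
#' @slot distance distance tag, always "cityblock"
#' @slot seed RNG seed used for initialization
#' @slot objective per-iteration L1 objective trace (non-increasing)
#' @export
setClass("NoiseletCodebook",
  representation(centroids = "matrix", patchSize = "integer",
                 distance = "character", seed = "integer",
                 objective = "numeric"),
  validity = function(object) {
    K <- nrow(object@centroids)
    if (K < 1L) return("codebook must have at least one centroid")
    if (!all(is.finite(object@centroids))) return("centroids must be finite")
    if (ncol(object@centroids) != 2L * object@patchSize^2)
      return("centroid dimension inconsistent with patch size")
    if (!identical(object@distance, "cityblock")) return("distance must be cityblock")
    TRUE
  }
)

#' AdaBoost tile denoiser
#'
#' Binary nuclei vs non-nuclei tile classifier: a weighted vote of
#' depth-1 decision stumps over the bins of the tile's codeword histogram.
#'
#' @slot featureIdx histogram bin used by each stump
#' @slot thresholds stump split threshold per round
#' @slot polarity +1 or -1 per round (+1 predicts nuclei when count > threshold)
#' @slot alphas positive stump weights
#' @slot nRounds number of boosting rounds actually kept
#' @slot patchSize,tileSize,nCodes configuration the model was trained under
#' @slot trainErrors ensemble training error after each round
#' @slot seed RNG seed recorded for provenance
#' @export
setClass("TileDenoiser",
  representation(featureIdx = "integer", thresholds = "numeric",
                 polarity = "numeric", alphas = "numeric", nRounds = "integer",
                 patchSize = "integer", tileSize = "integer", nCodes = "integer",
                 trainErrors = "numeric", seed = "integer"),
  validity = function(object) {
    n <- object@nRounds
    if (length(object@featureIdx) != n || length(object@thresholds) != n ||
        length(object@polarity) != n || length(object@alphas) != n)
      return("stump vectors must all have length nRounds")
    if (any(!is.finite(object@alphas)) || any(object@alphas < 0))
      return("stump weights must be finite and non-negative")
    if (!all(object@polarity %in% c(-1, 1))) return("polarity must be +/-1")
    TRUE
  }
)

#' Labeled nuclei segmentation
#'
#' @slot labels H x W integer mask, 0 = background, 1..n = nuclei instances
#' @slot centroids n x 2 matrix of (row, col) region centroids
#' @slot stats data.frame with per-region area, roundness and solidity
#' @export
setClass("NucleiSegmentation",
  representation(labels = "matrix", centroids = "matrix", stats = "data.frame"),
  validity = function(object) {
    lab <- object@labels
    n <- max(0L, lab)
    present <- sort(unique(as.vector(lab[lab > 0L])))
    if (n > 0L && !identical(present, seq_len(n)))
      return("labels must be contiguous 1..n")
    if (nrow(object@centroids) != n) return("one centroid per region required")
    if (nrow(object@stats) != n) return("one stats row per region required")
    if (n > 0L) {
      for (i in seq_len(n)) {
        w <- which(lab == i, arr.ind = TRUE)
        ci <- object@centroids[i, ]
        if (ci[1] < min(w[, 1]) - 0.5 || ci[1] > max(w[, 1]) + 0.5 ||
            ci[2] < min(w[, 2]) - 0.5 || ci[2] > max(w[, 2]) + 0.5)
          return("centroid outside region bounding box")
      }
    }
    TRUE
  }
)

#' Synthetic H&E field of view
#'
#' @slot image H x W x 3 RGB array, intensities in [0, background]
#' @slot mask H x W integer instance mask of the generated nuclei
#' @slot centroids n x 2 matrix of true nucleus centroids (row, col)
#' @slot params parameter list used by the generator (echo)
#' @export
setClass("HESample",
  representation(image = "array", mask = "matrix", centroids = "matrix",
                 params = "list"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
    if (!all(dim(object@mask) == d[1:2])) return("mask shape must match image")
    n <- max(0L, object@mask)
    if (nrow(object@centroids) != n) return("one centroid per mask instance")
    TRUE
  }
)
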