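#' Parameters for the synthetic H&E generator
#'
#' Defaults emulate a 40x field of view: blob-like hematoxylin-dominant
#' nuclei (10-35 px radii, i.e. 20 x 20 to 70 x 70 px bounding boxes)
#' with near-normal or bimodal intensity histograms, over an
#' eosin-dominant background whose texture presets produce a much
#' flatter hematoxylin spectrum (oriented sinusoidal fibers for
#' `fibrous_stroma`, dense smudges for `fold_artifact`, both for
#' `mixed`).
#'
#' @param imageSize (H, W) in pixels
#' @param nNuclei number of nuclei to place; a length-2 vector is a
#'   (min, max) range from which the count is drawn per field, so
#'   nucleus counts vary across a dataset as they do across real fields
#'   of view
#' @param radiusRange (min, max) nucleus radius in px
#' @param eccentricityRange (min, max) minor/major axis ratio
#' @param hemaNucleiMean range of per-nucleus mean hematoxylin concentration
#' @param hemaNucleiSd within-nucleus concentration spread
#' @param bimodalProb probability a nucleus gets a two-component
#'   (chromatin-clump) intensity histogram
#' @param bimodalShift half-distance between the two modes
#' @param hemaBackgroundBase baseline hematoxylin of clean background
#' @param eosinBackground baseline eosin concentration of background
#' @param background texture preset: `"flat"`, `"fibrous_stroma"`,
#'   `"fold_artifact"` or `"mixed"`
#' @param noiseSd pixel-wise Gaussian noise on concentrations
#' @param stainMatrix 3 x 2 OD stain matrix used for rendering
#' @param backgroundIntensity white level (default 255)
#' @param minSeparation minimum gap between nuclei in px
#' @param seed RNG seed fixing all randomness
#' @return named parameter list of class `syntheticParams`
#' @export
syntheticParams <- function(imageSize = c(512L, 512L), nNuclei = c(20L, 40L),
                            radiusRange = c(10, 35),
                            eccentricityRange = c(0.6, 1),
                            hemaNucleiMean = c(0.55, 0.85),
                            hemaNucleiSd = 0.07, bimodalProb = 0.4,
                            bimodalShift = 0.15,
                            hemaBackgroundBase = 0.04,
                            eosinBackground = 0.35,
                            background = c("mixed", "flat", "fibrous_stroma",
                                           "fold_artifact"),
                            noiseSd = 0.02,
                            stainMatrix = defaultStainMatrix(),
                            backgroundIntensity = 255,
                            minSeparation = 6, seed = 1L) {
  background <- match.arg(background)
  if (any(radiusRange <= 0) || any(nNuclei < 0))
    stop("radii must be positive and nNuclei non-negative", call. = FALSE)
  structure(list(imageSize = as.integer(imageSize), nNuclei = as.integer(nNuclei),
                 radiusRange = radiusRange, eccentricityRange = eccentricityRange,
                 hemaNucleiMean = hemaNucleiMean, hemaNucleiSd = hemaNucleiSd,
                 bimodalProb = bimodalProb, bimodalShift = bimodalShift,
                 hemaBackgroundBase = hemaBackgroundBase,
                 eosinBackground = eosinBackground, background = background,
                 noiseSd = noiseSd, stainMatrix = stainMatrix,
                 backgroundIntensity = backgroundIntensity,
                 minSeparation = minSeparation, seed = as.integer(seed)),
            class = "syntheticParams")
}

# oriented sinusoidal fiber texture in [0, 1]; few components keep the
# intensity histogram broad (near-arcsine), emulating the flat spectrum
# of stromal texture
.fiberTexture <- function(H, W, nFibers = 2L) {
  ri <- matrix(rep(seq_len(H), W), H, W)
  ci <- matrix(rep(seq_len(W), each = H), H, W)
  tex <- matrix(0, H, W)
  for (j in seq_len(nFibers)) {
    theta <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 0.12, 0.28)   # 4-8 px fibril period at 40x
    phase <- stats::runif(1, 0, 2 * pi)
    tex <- tex + sin(2 * pi * freq * (ci * cos(theta) + ri * sin(theta)) +
                     phase)
  }
  (tex / nFibers + 1) / 2
}

# anisotropic Gaussian smudges (tissue folds), peak-normalized to [0, 1]
.foldTexture <- function(H, W, nFolds = 2L) {
  ri <- matrix(rep(seq_len(H), W), H, W)
  ci <- matrix(rep(seq_len(W), each = H), H, W)
  tex <- matrix(0, H, W)
  for (j in seq_len(nFolds)) {
    cy <- stats::runif(1, 0.15 * H, 0.85 * H)
    cx <- stats::runif(1, 0.15 * W, 0.85 * W)
    theta <- stats::runif(1, 0, pi)
    sLong <- stats::runif(1, 0.12, 0.25) * min(H, W)
    sShort <- stats::runif(1, 0.03, 0.07) * min(H, W)
    u <- (ci - cx) * cos(theta) + (ri - cy) * sin(theta)
    v <- -(ci - cx) * sin(theta) + (ri - cy) * cos(theta)
    tex <- pmax(tex, exp(-(u^2 / (2 * sLong^2) + v^2 / (2 * sShort^2))))
  }
  tex
}

#' Generate one synthetic H&E field of view
#'
#' Places non-overlapping ellipses with hematoxylin-dominant
#' concentrations (unimodal Gaussian or two-component chromatin
#' texture), adds the chosen background texture with an eosin-dominant,
#' spectrally flat hematoxylin component, and renders RGB through
#' Beer-Lambert with the configured stain matrix. Fully reproducible
#' from the seed.
#'
#' @param params a [syntheticParams()] list
#' @return an [HESample-class] with image, instance mask and centroids
#' @export
generateSample <- function(params = syntheticParams()) {
  stopifnot(inherits(params, "syntheticParams"))
  p <- params
  H <- p$imageSize[1]; W <- p$imageSize[2]
  .withSeed(p$seed, {
    if (length(p$nNuclei) == 2L)
      p$nNuclei <- sample(p$nNuclei[1]:p$nNuclei[2], 1L)
    mask <- matrix(0L, H, W)
    blocked <- matrix(FALSE, H, W)    # nuclei dilated by minSeparation
    ri <- matrix(rep(seq_len(H), W), H, W)
    ci <- matrix(rep(seq_len(W), each = H), H, W)
    placed <- 0L
    tries <- 0L
    maxTries <- 300L * max(1L, p$nNuclei)
    nucleusInfo <- list()
    while (placed < p$nNuclei) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place ", p$nNuclei, " non-overlapping nuclei in a ",
             H, "x", W, " image after ", maxTries, " attempts", call. = FALSE)
      r <- stats::runif(1, p$radiusRange[1], p$radiusRange[2])
      ecc <- stats::runif(1, p$eccentricityRange[1], p$eccentricityRange[2])
      a <- r / sqrt(ecc); b <- r * sqrt(ecc)     # major/minor semi-axes
      theta <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, a + 2, H - a - 2)
      cx <- stats::runif(1, a + 2, W - a - 2)
      u <- (ci - cx) * cos(theta) + (ri - cy) * sin(theta)
      v <- -(ci - cx) * sin(theta) + (ri - cy) * cos(theta)
      q <- u^2 / a^2 + v^2 / b^2
      inside <- q <= 1
      if (any(blocked[inside])) next
      placed <- placed + 1L
      mask[inside] <- placed
      gap <- p$minSeparation
      blocked[q <= (1 + gap / min(a, b))^2] <- TRUE
      nucleusInfo[[placed]] <- list(inside = which(inside))
    }

    # background concentration maps
    cH <- matrix(p$hemaBackgroundBase, H, W)
    cE <- matrix(p$eosinBackground, H, W)
    if (p$background %in% c("fibrous_stroma", "mixed")) {
      # independent hematoxylin-tinged and eosin-dominant fiber systems:
      # collagen is mostly eosin, cellular stroma carries hematoxylin
      cH <- cH + 0.38 * .fiberTexture(H, W)
      cE <- cE + 0.30 * .fiberTexture(H, W)
    }
    if (p$background %in% c("fold_artifact", "mixed")) {
      fold <- .foldTexture(H, W, nFolds = if (p$background == "mixed") 2L else 3L)
      cH <- cH + 0.55 * fold
      cE <- cE + 0.45 * fold
    }

    # nuclei concentrations: unimodal or bimodal hematoxylin
    for (i in seq_along(nucleusInfo)) {
      px <- nucleusInfo[[i]]$inside
      mu <- stats::runif(1, p$hemaNucleiMean[1], p$hemaNucleiMean[2])
      if (stats::runif(1) < p$bimodalProb) {
        clump <- stats::rbinom(length(px), 1, 0.5)
        vals <- mu + ifelse(clump == 1, p$bimodalShift, -p$bimodalShift) +
          stats::rnorm(length(px), 0, p$hemaNucleiSd / 2)
      } else {
        vals <- stats::rnorm(length(px), mu, p$hemaNucleiSd)
      }
      cH[px] <- pmax(0.15, vals)
      cE[px] <- 0.10
    }

    if (p$noiseSd > 0) {
      cH <- cH + stats::rnorm(H * W, 0, p$noiseSd)
      cE <- cE + stats::rnorm(H * W, 0, p$noiseSd)
    }
    cH <- pmax(cH, 0); cE <- pmax(cE, 0)

    # Beer-Lambert rendering, 8-bit quantization
    conc <- rbind(as.vector(cH), as.vector(cE))
    od <- p$stainMatrix %*% conc
    img <- array(0, c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- matrix(p$backgroundIntensity * exp(-od[ch, ]), H, W)
    img <- round(pmin(pmax(img, 0), p$backgroundIntensity))

    new("HESample", image = img, mask = mask,
        centroids = .regionCentroids(mask), params = unclass(p))
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Derives one sub-seed per image from the master seed, so the dataset
#' is deterministic and each image differs.
#'
#' @param nImages number of fields of view (>= 1)
#' @param params shared [syntheticParams()]; the per-image seed is replaced
#' @param seed master seed
#' @return list of [HESample-class] objects
#' @export
generateDataset <- function(nImages, params = syntheticParams(), seed = 1L) {
  nImages <- .assertScalarInt(nImages, "nImages")
  if (nImages < 1L) stop("nImages must be >= 1", call. = FALSE)
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, nImages))
  lapply(seq_len(nImages), function(i) {
    pi <- params
    pi$seed <- seeds[i]
    generateSample(pi)
  })
}
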