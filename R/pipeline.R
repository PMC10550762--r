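#' Construct and validate a pipeline configuration
#'
#' The experimental grid allows patch sizes 2/4/8, tile sizes
#' 8/12/16/20/24 and 2/4/8/16 codes; a configuration is valid only when
#' the patch size divides the tile size.
#'
#' @param patchSize noiselet patch side (2, 4 or 8)
#' @param tileSize classification tile side (8, 12, 16, 20 or 24)
#' @param nCodes code-book size (2, 4, 8 or 16)
#' @param seed master seed for codebook/denoiser training
#' @param nRounds AdaBoost rounds
#' @param maxFeatures patch-feature subsample cap for codebook k-means
#' @param overlapThreshold tile-labeling pixel fraction: a training tile
#'   counts as nuclei when at least this fraction of its pixels is
#'   nuclear. Kept low (0.05) so nucleus-border tiles are learned as
#'   signal; labeling them as background teaches the classifier to
#'   blank nucleus rims, which clips every segmented nucleus
#' @param segmenter segmenter settings, see [segmenterParams()]
#' @return validated config list of class `pipelineConfig`
#' @export
pipelineConfig <- function(patchSize = 4L, tileSize = 12L, nCodes = 8L,
                           seed = 1L, nRounds = 50L, maxFeatures = 4000L,
                           overlapThreshold = 0.05,
                           segmenter = segmenterParams()) {
  cfg <- structure(list(patchSize = as.integer(patchSize),
                        tileSize = as.integer(tileSize),
                        nCodes = as.integer(nCodes), seed = as.integer(seed),
                        nRounds = as.integer(nRounds),
                        maxFeatures = as.integer(maxFeatures),
                        overlapThreshold = overlapThreshold,
                        segmenter = segmenter),
                   class = "pipelineConfig")
  validateConfig(cfg)
}

#' @rdname pipelineConfig
#' @param cfg a `pipelineConfig` list
#' @export
validateConfig <- function(cfg) {
  if (!cfg$patchSize %in% c(2L, 4L, 8L))
    stop("patchSize must be one of 2, 4, 8 (got ", cfg$patchSize, ")",
         call. = FALSE)
  if (!cfg$tileSize %in% c(8L, 12L, 16L, 20L, 24L))
    stop("tileSize must be one of 8, 12, 16, 20, 24 (got ", cfg$tileSize, ")",
         call. = FALSE)
  if (!cfg$nCodes %in% c(2L, 4L, 8L, 16L))
    stop("nCodes must be one of 2, 4, 8, 16 (got ", cfg$nCodes, ")",
         call. = FALSE)
  if (cfg$tileSize %% cfg$patchSize != 0L)
    stop("incompatible configuration: patch size ", cfg$patchSize,
         " does not divide tile size ", cfg$tileSize, call. = FALSE)
  cfg
}

#' Enumerate the valid experimental parameter grid
#'
#' Full cross of patch sizes {2,4,8}, tile sizes {8,12,16,20,24} and
#' code counts {2,4,8,16}, keeping only combinations where the patch
#' size divides the tile size (52 of the 60 cells).
#'
#' @return data.frame with columns patchSize, tileSize, nCodes
#' @export
parameterGrid <- function() {
  g <- expand.grid(patchSize = c(2L, 4L, 8L),
                   tileSize = c(8L, 12L, 16L, 20L, 24L),
                   nCodes = c(2L, 4L, 8L, 16L))
  g <- g[g$tileSize %% g$patchSize == 0L, , drop = FALSE]
  g <- g[order(g$patchSize, g$tileSize, g$nCodes), ]
  rownames(g) <- NULL
  g
}

# hematoxylin map + patch features for each sample, computed once
.prepareSamples <- function(samples, patchSize, segParams) {
  basis <- noiseletBasis(patchSize)
  lapply(samples, function(s) {
    stains <- estimateStainMatrix(sampleImage(s), segParams$alphaPercentile,
                                  segParams$odThreshold, segParams$background)
    hema <- separateHematoxylin(sampleImage(s), stains, segParams$background)
    list(sample = s, stains = stains, hema = hema, basis = basis)
  })
}

# codebook + denoiser trained on the given prepared samples
.trainFold <- function(prep, cfg) {
  basis <- prep[[1]]$basis
  feats <- lapply(prep, function(pr) {
    grid <- tileImage(pr$hema, cfg$tileSize)
    crop <- pr$hema[seq_len(grid$gridRows * cfg$tileSize),
                    seq_len(grid$gridCols * cfg$tileSize), drop = FALSE]
    .patchFeatureMatrix(crop, basis)
  })
  allFeats <- do.call(rbind, feats)
  if (nrow(allFeats) > cfg$maxFeatures) {
    idx <- .withSeed(cfg$seed, sample.int(nrow(allFeats), cfg$maxFeatures))
    sub <- allFeats[idx, , drop = FALSE]
  } else sub <- allFeats
  book <- buildCodebook(sub, cfg$nCodes, seed = cfg$seed,
                        patchSize = cfg$patchSize)
  hists <- list(); labs <- list()
  for (i in seq_along(prep)) {
    grid <- tileImage(prep[[i]]$hema, cfg$tileSize)
    hists[[i]] <- encodeTiles(prep[[i]]$hema, grid, book, basis)
    labs[[i]] <- labelTiles(grid, nucleiMask(prep[[i]]$sample),
                            cfg$overlapThreshold)
  }
  model <- trainDenoiser(do.call(rbind, hists), unlist(labs),
                         nRounds = cfg$nRounds, seed = cfg$seed,
                         patchSize = cfg$patchSize, tileSize = cfg$tileSize)
  list(book = book, model = model)
}

#' Run a leave-one-out denoising experiment
#'
#' For each image in turn: the code-book and AdaBoost denoiser are
#' trained on the remaining images, the held-out image is segmented with
#' and without denoising, and detection F-score, Dice and nucleus counts
#' are recorded against the ground truth.
#'
#' @param samples list of [HESample-class] objects (>= 2)
#' @param cfg a [pipelineConfig()]
#' @param denoise set `FALSE` to run the baseline only
#' @return list with `perImage` (data.frame), `summary` (mean scores) and
#'   `correlation` (annotated vs detected-after-denoising counts; `NA`
#'   when undefined)
#' @export
runExperiment <- function(samples, cfg = pipelineConfig(), denoise = TRUE) {
  if (length(samples) < 2L)
    stop("leave-one-out validation requires at least 2 images", call. = FALSE)
  cfg <- validateConfig(cfg)
  prep <- .prepareSamples(samples, cfg$patchSize, cfg$segmenter)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    gtSeg <- segmentationFromMask(nucleiMask(s))
    base <- segmentNuclei(sampleImage(s), cfg$segmenter,
                          stains = prep[[i]]$stains)
    mBase <- matchNuclei(base, gtSeg)
    dBase <- diceScore(labelMask(base) > 0, nucleiMask(s) > 0)
    row <- data.frame(image = i, nTrue = nucleiCount(gtSeg),
                      fBaseline = mBase$f1, diceBaseline = dBase,
                      nBaseline = nucleiCount(base))
    if (denoise) {
      fold <- .trainFold(prep[-i], cfg)
      den <- segmentNuclei(sampleImage(s), cfg$segmenter,
                           denoiser = fold$model, codebook = fold$book,
                           stains = prep[[i]]$stains)
      mDen <- matchNuclei(den, gtSeg)
      row$fDenoised <- mDen$f1
      row$diceDenoised <- diceScore(labelMask(den) > 0, nucleiMask(s) > 0)
      row$nDenoised <- nucleiCount(den)
    }
    rows[[i]] <- row
  }
  perImage <- do.call(rbind, rows)
  summary <- colMeans(perImage[, setdiff(names(perImage), "image")])
  correlation <- NA_real_
  if (denoise)
    correlation <- tryCatch(
      countCorrelation(perImage$nTrue, perImage$nDenoised),
      error = function(e) NA_real_)
  list(perImage = perImage, summary = as.list(summary),
       correlation = correlation)
}

#' Exhaustive parameter grid search
#'
#' Runs [runExperiment()] for every valid configuration of the grid and
#' ranks results by mean denoised F-score (ties: denoised Dice, then
#' lexicographic configuration order).
#'
#' @param samples list of [HESample-class] objects
#' @param grid data.frame of configurations, default [parameterGrid()]
#' @param baseConfig settings shared by all runs (patch/tile/codes are
#'   overridden per grid row)
#' @return data.frame of one ranked row per configuration
#' @export
gridSearch <- function(samples, grid = parameterGrid(),
                       baseConfig = pipelineConfig()) {
  if (nrow(grid) == 0L) stop("the parameter grid is empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- baseConfig
    cfg$patchSize <- grid$patchSize[i]
    cfg$tileSize <- grid$tileSize[i]
    cfg$nCodes <- grid$nCodes[i]
    cfg <- validateConfig(cfg)
    res <- runExperiment(samples, cfg)
    data.frame(patchSize = cfg$patchSize, tileSize = cfg$tileSize,
               nCodes = cfg$nCodes,
               fBaseline = res$summary$fBaseline,
               fDenoised = res$summary$fDenoised,
               diceBaseline = res$summary$diceBaseline,
               diceDenoised = res$summary$diceDenoised,
               correlation = res$correlation)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fDenoised, -out$diceDenoised, out$patchSize,
                   out$tileSize, out$nCodes), ]
  rownames(out) <- NULL
  out
}
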