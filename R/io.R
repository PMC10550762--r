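# EBImage stores images as (x, y[, channel]); the package works in
# (row, col) matrices, so IO converts between the two conventions.

#' Read an RGB image
#'
#' @param path PNG/TIFF file
#' @param background white level used to rescale to intensities
#' @return H x W x 3 array of intensities in [0, background]
#' @export
readRGBImage <- function(path, background = 255) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2L, 1L, 3L)) * background
}

#' Write an RGB image
#' @param image H x W x 3 array in [0, background]
#' @inheritParams readRGBImage
#' @export
writeRGBImage <- function(image, path, background = 255) {
  EBImage::writeImage(
    EBImage::Image(aperm(image / background, c(2L, 1L, 3L)),
                   colormode = "Color"), path)
  invisible(path)
}

#' Write a hematoxylin concentration map
#'
#' Rescales to [0, 1] by `maxValue` (defaults to the map maximum) and
#' writes an 8-bit grayscale image.
#'
#' @param hema H x W non-negative matrix
#' @param path output PNG/TIFF
#' @param maxValue concentration mapped to white
#' @export
writeHematoxylin <- function(hema, path, maxValue = NULL) {
  maxValue <- maxValue %||% max(hema, 1e-9)
  EBImage::writeImage(EBImage::Image(t(pmin(hema / maxValue, 1))), path)
  invisible(path)
}

#' Write / read a 16-bit instance label mask
#' @param labels H x W integer mask (0 = background)
#' @param path TIFF/PNG file
#' @export
writeLabelMask <- function(labels, path) {
  EBImage::writeImage(EBImage::Image(t(labels) / 65535), path,
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  a <- as.array(EBImage::readImage(path))
  m <- t(round(a * 65535))
  storage.mode(m) <- "integer"
  m
}

#' Write / read centroids as CSV
#' @param seg a [NucleiSegmentation-class]
#' @param path CSV file with columns label,row,col,area,roundness,solidity
#' @export
writeCentroids <- function(seg, path) {
  st <- regionStats(seg)
  df <- data.frame(label = seq_len(nucleiCount(seg)),
                   row = centroids(seg)[, 1], col = centroids(seg)[, 2],
                   area = st$area, roundness = st$roundness,
                   solidity = st$solidity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCentroids
#' @export
readCentroids <- function(path) {
  utils::read.csv(path)
}

#' Serialize a stain matrix, code-book or denoiser model to JSON
#' @param x object to serialize
#' @param path JSON file
#' @export
writeStainMatrix <- function(x, path) {
  jsonlite::write_json(list(hematoxylin = x[, 1], eosin = x[, 2]), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeStainMatrix
#' @export
readStainMatrix <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- cbind(hematoxylin = j$hematoxylin, eosin = j$eosin)
  rownames(M) <- c("R", "G", "B")
  M
}

#' @rdname writeStainMatrix
#' @export
writeCodebook <- function(x, path) {
  stopifnot(is(x, "NoiseletCodebook"))
  jsonlite::write_json(list(centroids = x@centroids, patchSize = x@patchSize,
                            distance = x@distance, seed = x@seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeStainMatrix
#' @export
readCodebook <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NoiseletCodebook", centroids = j$centroids,
      patchSize = as.integer(j$patchSize), distance = j$distance,
      seed = as.integer(j$seed), objective = numeric(0))
}

#' @rdname writeStainMatrix
#' @export
writeDenoiser <- function(x, path) {
  stopifnot(is(x, "TileDenoiser"))
  jsonlite::write_json(
    list(featureIdx = x@featureIdx, thresholds = x@thresholds,
         polarity = x@polarity, alphas = x@alphas, nRounds = x@nRounds,
         patchSize = x@patchSize, tileSize = x@tileSize, nCodes = x@nCodes,
         trainErrors = x@trainErrors, seed = x@seed),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeStainMatrix
#' @export
readDenoiser <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  int1 <- function(x) if (is.null(x) || length(x) == 0L) NA_integer_
                      else as.integer(x)
  vec <- function(x, mode) if (is.null(x)) vector(mode, 0L)
                           else as.vector(x, mode)
  new("TileDenoiser", featureIdx = vec(j$featureIdx, "integer"),
      thresholds = vec(j$thresholds, "numeric"),
      polarity = vec(j$polarity, "numeric"),
      alphas = vec(j$alphas, "numeric"), nRounds = int1(j$nRounds),
      patchSize = int1(j$patchSize), tileSize = int1(j$tileSize),
      nCodes = int1(j$nCodes), trainErrors = vec(j$trainErrors, "numeric"),
      seed = int1(j$seed))
}

#' Write a synthetic sample into a dataset directory layout
#'
#' Creates `images/<name>.png`, `masks/<name>.tif`,
#' `centroids/<name>.csv` and `params/<name>.yml` under `dir`.
#'
#' @param sample an [HESample-class]
#' @param dir dataset root directory
#' @param name basename for the files
#' @export
writeSample <- function(sample, dir, name) {
  for (d in c("images", "masks", "centroids", "params"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  writeRGBImage(sampleImage(sample), file.path(dir, "images",
                paste0(name, ".png")),
                sample@params$backgroundIntensity)
  writeLabelMask(nucleiMask(sample), file.path(dir, "masks",
                 paste0(name, ".tif")))
  utils::write.csv(data.frame(label = seq_len(nrow(centroids(sample))),
                              row = centroids(sample)[, 1],
                              col = centroids(sample)[, 2]),
                   file.path(dir, "centroids", paste0(name, ".csv")),
                   row.names = FALSE)
  pr <- sample@params
  pr$stainMatrix <- as.vector(pr$stainMatrix)
  yaml::write_yaml(pr, file.path(dir, "params", paste0(name, ".yml")))
  invisible(dir)
}
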