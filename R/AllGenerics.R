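#' @rdname NoiseletBasis-class
#' @param object,x a package object
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname NoiseletBasis-class
#' @export
setGeneric("basisSize", function(x) standardGeneric("basisSize"))

#' @rdname NoiseletCodebook-class
#' @export
setGeneric("codewords", function(x) standardGeneric("codewords"))

#' @rdname NoiseletCodebook-class
#' @export
setGeneric("codebookSize", function(x) standardGeneric("codebookSize"))

#' @rdname NucleiSegmentation-class
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' @rdname NucleiSegmentation-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname NucleiSegmentation-class
#' @export
setGeneric("nucleiCount", function(x) standardGeneric("nucleiCount"))

#' @rdname NucleiSegmentation-class
#' @export
setGeneric("regionStats", function(x) standardGeneric("regionStats"))

#' @rdname HESample-class
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))

#' @rdname HESample-class
#' @export
setGeneric("nucleiMask", function(x) standardGeneric("nucleiMask"))

#' @describeIn NoiseletBasis-class basis matrix accessor
setMethod("basisMatrix", "NoiseletBasis", function(x) x@matrix)

#' @describeIn NoiseletBasis-class basis size accessor
setMethod("basisSize", "NoiseletBasis", function(x) x@size)

#' @describeIn NoiseletCodebook-class centroid matrix accessor
setMethod("codewords", "NoiseletCodebook", function(x) x@centroids)

#' @describeIn NoiseletCodebook-class number of codes K
setMethod("codebookSize", "NoiseletCodebook", function(x) nrow(x@centroids))

#' @describeIn NucleiSegmentation-class integer label mask accessor
setMethod("labelMask", "NucleiSegmentation", function(x) x@labels)

#' @describeIn NucleiSegmentation-class region centroids (row, col)
setMethod("centroids", "NucleiSegmentation", function(x) x@centroids)

#' @describeIn HESample-class true nucleus centroids (row, col)
setMethod("centroids", "HESample", function(x) x@centroids)

#' @describeIn NucleiSegmentation-class number of segmented nuclei
setMethod("nucleiCount", "NucleiSegmentation", function(x) max(0L, x@labels))

#' @describeIn NucleiSegmentation-class per-region shape statistics
setMethod("regionStats", "NucleiSegmentation", function(x) x@stats)

#' @describeIn HESample-class RGB image array accessor
setMethod("sampleImage", "HESample", function(x) x@image)

#' @describeIn HESample-class instance mask accessor
setMethod("nucleiMask", "HESample", function(x) x@mask)

setMethod("show", "NoiseletBasis", function(object) {
  cat("NoiseletBasis of size", object@size, "(unitary,",
      "entry magnitude", format(1 / sqrt(object@size), digits = 4), ")\n")
})

setMethod("show", "NoiseletCodebook", function(object) {
  cat("NoiseletCodebook:", nrow(object@centroids), "codes of dimension",
      ncol(object@centroids), "(patch", paste0(object@patchSize, "x",
      object@patchSize), "city-block k-means, seed", object@seed, ")\n")
})

setMethod("show", "TileDenoiser", function(object) {
  cat("TileDenoiser: AdaBoost with", object@nRounds, "stumps on",
      object@nCodes, "histogram bins (tile",
      paste0(object@tileSize, "x", object@tileSize), "patch",
      paste0(object@patchSize, "x", object@patchSize), ")\n")
  if (object@nRounds > 0)
    cat("  final training error:",
        format(utils::tail(object@trainErrors, 1), digits = 4), "\n")
})

setMethod("show", "NucleiSegmentation", function(object) {
  cat("NucleiSegmentation:", nucleiCount(object), "nuclei in a",
      paste(dim(object@labels), collapse = " x "), "frame\n")
})

setMethod("show", "HESample", function(object) {
  d <- dim(object@image)
  cat("HESample:", paste0(d[1], "x", d[2]), "RGB field with",
      max(0L, object@mask), "nuclei (background preset:",
      object@params$background %||% "?", ")\n")
})
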