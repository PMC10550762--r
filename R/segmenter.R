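#' Fast radial symmetry transform (dark blobs)
#'
#' Loy-Zelinsky-style gradient voting: every pixel with gradient
#' magnitude above `gradientThreshold * max` casts a vote r pixels
#' against its gradient direction (toward the center of a dark blob on a
#' light background). Per radius, the orientation count O (clipped at
#' kappa) and magnitude sum M form (O/kappa)^alpha * (M/kappa), smoothed
#' by a Gaussian of width proportional to r; the map is the mean over
#' radii, positive at dark blob centers.
#'
#' @param image H x W numeric matrix (e.g. hematoxylin, nuclei dark means
#'   high values are voted via the negated map internally; pass intensity
#'   where blobs are dark, such as `max(h) - h` for concentration maps)
#' @param radii positive integer radii to probe
#' @param alpha radial-strictness exponent (default 2)
#' @param gradientThreshold fraction of the maximum gradient magnitude
#'   below which pixels do not vote (default 0.05)
#' @param excludeMask optional logical H x W matrix; gradients at `TRUE`
#'   pixels cast no votes (used to ignore artificial edges at the
#'   boundary of blanked tiles)
#' @return H x W numeric symmetry map with attribute `radii`
#' @export
fastRadialSymmetry <- function(image, radii, alpha = 2,
                               gradientThreshold = 0.05,
                               excludeMask = NULL) {
  if (length(radii) == 0L || any(radii < 1))
    stop("radii must be a non-empty set of positive integers", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  gy <- matrix(0, H, W); gx <- matrix(0, H, W)
  gy[2:(H - 1), ] <- (image[3:H, ] - image[1:(H - 2), ]) / 2
  gx[, 2:(W - 1)] <- (image[, 3:W] - image[, 1:(W - 2)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (!is.null(excludeMask)) mag[excludeMask] <- 0
  thr <- gradientThreshold * max(mag)
  sel <- which(mag > thr & mag > 0)
  S <- matrix(0, H, W)
  if (length(sel) == 0L) {
    attr(S, "radii") <- as.integer(radii)
    attr(S, "scale") <- matrix(radii[1], H, W)
    return(S)
  }
  r0 <- (sel - 1L) %% H + 1L
  c0 <- (sel - 1L) %/% H + 1L
  uy <- gy[sel] / mag[sel]
  ux <- gx[sel] / mag[sel]
  mg <- mag[sel]
  bestVal <- matrix(-Inf, H, W)      # dominant radius per pixel
  bestR <- matrix(radii[1], H, W)
  for (r in radii) {
    rr <- r0 - round(r * uy)          # negatively-affected pixel: blob center
    cc <- c0 - round(r * ux)
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    lin <- rr[ok] + (cc[ok] - 1L) * H
    O <- tabulate(lin, H * W)
    M <- numeric(H * W)
    ms <- rowsum(mg[ok], lin)
    M[as.integer(rownames(ms))] <- ms
    kappa <- if (r == 1) 8 else 9.9
    Fm <- matrix((pmin(O, kappa) / kappa)^alpha * (M / kappa), H, W)
    Sm <- EBImage::gblur(Fm, sigma = max(0.5, 0.25 * r))
    upd <- Sm > bestVal
    bestVal[upd] <- Sm[upd]
    bestR[upd] <- r
    S <- S + Sm
  }
  S <- S / length(radii)
  attr(S, "radii") <- as.integer(radii)
  attr(S, "scale") <- bestR
  S
}

#' Detect marker points from a symmetry map
#'
#' Pixels above `relThreshold * max(map)` are grouped into connected
#' components; each component contributes its maximum as one candidate
#' (so a ridge of secondary maxima inside one blob yields a single
#' marker), followed by greedy non-maximum suppression so no two
#' markers lie within `minDistance` pixels (Euclidean).
#'
#' @param map symmetry map from [fastRadialSymmetry()]
#' @param minDistance suppression radius in pixels
#' @param relThreshold fraction of the map maximum, in (0, 1]
#' @return integer matrix of marker (row, col) positions, possibly empty
#' @export
detectMarkers <- function(map, minDistance = 10, relThreshold = 0.2) {
  if (relThreshold <= 0 || relThreshold > 1)
    stop("relThreshold must be in (0, 1]", call. = FALSE)
  mx <- max(map)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (mx <= 0) return(empty)
  comp <- EBImage::bwlabel(map >= relThreshold * mx)
  ncomp <- max(comp)
  cand <- matrix(0L, ncomp, 2)
  for (k in seq_len(ncomp)) {
    px <- which(comp == k)
    peak <- px[which.max(map[px])]
    cand[k, ] <- c((peak - 1L) %% nrow(map) + 1L,
                   (peak - 1L) %/% nrow(map) + 1L)
  }
  if (nrow(cand) == 0L) return(empty)
  o <- order(-map[cand], cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(keep)) {
      kept <- cand[keep, , drop = FALSE]
      d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
      if (min(d2) < minDistance^2) next
    }
    keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

# per-region area/perimeter/roundness/solidity for a label mask
.regionShapeStats <- function(labels) {
  n <- max(0L, labels)
  if (n == 0L)
    return(data.frame(area = numeric(0), roundness = numeric(0),
                      solidity = numeric(0)))
  sh <- EBImage::computeFeatures.shape(labels)
  area <- sh[, "s.area"]
  perim <- pmax(sh[, "s.perimeter"], 1)
  roundness <- 4 * pi * area / perim^2
  solidity <- vapply(seq_len(n), function(i) {
    px <- which(labels == i, arr.ind = TRUE)
    if (nrow(px) < 3L) return(1)
    hull <- grDevices::chull(px[, 2], px[, 1])
    hx <- px[hull, 2]; hy <- px[hull, 1]
    k <- length(hull)
    if (k < 3L) return(1)
    shoelace <- abs(sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)) / 2
    hullPerim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    hullArea <- shoelace + hullPerim / 2 + 1   # pixel-count correction
    min(1, nrow(px) / hullArea)
  }, numeric(1))
  data.frame(area = as.numeric(area), roundness = as.numeric(roundness),
             solidity = solidity)
}

.regionCentroids <- function(labels) {
  n <- max(0L, labels)
  if (n == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  r <- (idx - 1L) %% nrow(labels) + 1L
  c <- (idx - 1L) %/% nrow(labels) + 1L
  cbind(row = as.vector(rowsum(r, lab) / tabulate(lab, n)),
        col = as.vector(rowsum(c, lab) / tabulate(lab, n)))
}

.makeSegmentation <- function(labels) {
  labels <- .relabel(labels)
  new("NucleiSegmentation", labels = labels,
      centroids = .regionCentroids(labels),
      stats = .regionShapeStats(labels))
}

# Merge adjacent regions when the union is rounder than both parts.
# Two halves of one nucleus split by duplicate markers are adjacent and
# merge into a rounder shape; two genuinely distinct touching regions
# merge into a peanut, which is less round, and are left alone.
.mergeSplitRegions <- function(labels, maxArea = Inf) {
  repeat {
    labels <- .relabel(labels)
    n <- max(0L, labels)
    if (n < 2L) return(labels)
    H <- nrow(labels)
    # adjacent label pairs via 4-neighbor shifts
    pairs <- unique(rbind(
      cbind(as.vector(labels[-H, ]), as.vector(labels[-1, ])),
      cbind(as.vector(labels[, -ncol(labels)]), as.vector(labels[, -1]))))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0L) return(labels)
    pairs <- unique(t(apply(pairs, 1, sort)))
    st <- .regionShapeStats(labels)
    merged <- FALSE
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (st$area[i] + st$area[j] > maxArea) next
      trial <- labels
      trial[trial == j] <- i
      sti <- .regionShapeStats((trial == i) * 1L)
      if (sti$roundness[1] > max(st$roundness[i], st$roundness[j])) {
        labels <- trial
        merged <- TRUE
        break
      }
    }
    if (!merged) return(labels)
  }
}

# renumber positive labels to contiguous 1..n
.relabel <- function(labels) {
  present <- sort(unique(as.vector(labels[labels > 0L])))
  if (length(present) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  lut <- integer(max(present))
  lut[present] <- seq_along(present)
  out <- labels
  out[out > 0L] <- lut[out[out > 0L]]
  storage.mode(out) <- "integer"
  out
}

#' Marker-controlled watershed on a hematoxylin map
#'
#' Grows one basin per marker on the hematoxylin concentration image
#' using seeded region growing on the image manifold
#' (`EBImage::propagate`), with an additional background basin seeded
#' from low-hematoxylin pixels (below `bgQuantile`, eroded) that is
#' discarded afterwards. At most one region per marker is returned.
#'
#' @param hema H x W non-negative hematoxylin concentration map
#' @param markers k x 2 integer matrix of (row, col) seeds
#' @param bgQuantile hematoxylin quantile defining background seeds
#' @param bgMask optional logical matrix of pixels known to be
#'   background (e.g. tiles blanked by the denoiser); they join the
#'   background basin so no nucleus region can grow across them
#' @return an (unfiltered) [NucleiSegmentation-class]
#' @export
markerWatershed <- function(hema, markers, bgQuantile = 0.25, bgMask = NULL) {
  H <- nrow(hema); W <- ncol(hema)
  if (is.null(dim(markers))) markers <- matrix(markers, ncol = 2)
  n <- nrow(markers)
  if (n == 0L) return(.makeSegmentation(matrix(0L, H, W)))
  if (any(markers[, 1] < 1 | markers[, 1] > H |
          markers[, 2] < 1 | markers[, 2] > W))
    stop("marker out of image bounds", call. = FALSE)
  seeds <- matrix(0L, H, W)
  bg <- hema < stats::quantile(hema, bgQuantile)
  bgEroded <- EBImage::erode(bg + 0, EBImage::makeBrush(5, "disc")) > 0
  if (!any(bgEroded)) bgEroded <- bg
  if (!is.null(bgMask)) bgEroded <- bgEroded | bgMask
  seeds[bgEroded] <- n + 1L
  seeds[cbind(markers[, 1], markers[, 2])] <- seq_len(n)
  lab <- EBImage::imageData(EBImage::propagate(hema, seeds))
  lab[lab == n + 1L] <- 0L
  storage.mode(lab) <- "integer"
  .makeSegmentation(lab)
}

#' Filter segmented regions by shape
#'
#' Removes regions whose area falls outside `areaRange`, whose roundness
#' (4 pi area / perimeter^2) is below `minRoundness`, or whose solidity
#' (area / convex area) is below `minSolidity`; remaining labels are
#' renumbered contiguously. Idempotent.
#'
#' @param seg a [NucleiSegmentation-class]
#' @param areaRange (min, max) region area in px^2
#' @param minRoundness,minSolidity minimum shape scores in [0, 1]
#' @return filtered [NucleiSegmentation-class]
#' @export
filterRegions <- function(seg, areaRange = c(250, 4900), minRoundness = 0.4,
                          minSolidity = 0.7) {
  stopifnot(is(seg, "NucleiSegmentation"))
  if (areaRange[1] > areaRange[2])
    stop("areaRange minimum exceeds maximum", call. = FALSE)
  st <- seg@stats
  keep <- which(st$area >= areaRange[1] & st$area <= areaRange[2] &
                st$roundness >= minRoundness & st$solidity >= minSolidity)
  lab <- seg@labels
  lab[!(lab %in% keep)] <- 0L
  .makeSegmentation(lab)
}

#' Default segmenter parameters
#'
#' Radii and area limits follow typical nucleus sizes at 40x
#' magnification (20 x 20 to 70 x 70 pixel bounding boxes).
#'
#' @return named list of segmenter settings
#' @export
segmenterParams <- function() {
  list(radii = c(5, 10, 15, 20, 25, 30, 35), alpha = 2,
       gradientThreshold = 0.05, smoothSigma = 2, mapSigma = 3,
       relThreshold = 0.15, minDistance = 10, bgQuantile = 0.25,
       areaRange = c(250, 4900), minRoundness = 0.4, minSolidity = 0.7,
       odThreshold = 0.15, alphaPercentile = 0.01, background = 255)
}

#' Segment nuclei in an H&E image
#'
#' Full baseline pipeline: stain separation, optional noiselet-denoising
#' (non-nuclei tiles of the hematoxylin map blanked before detection),
#' Gaussian smoothing, fast radial symmetry markers, marker-controlled
#' watershed and shape filtering.
#'
#' @param image H x W x 3 RGB array, or an H x W hematoxylin map
#' @param params list of settings, see [segmenterParams()]
#' @param denoiser optional [TileDenoiser-class]; requires `codebook`
#' @param codebook the [NoiseletCodebook-class] the denoiser was trained with
#' @param stains optional fixed 3 x 2 stain matrix (estimated per image
#'   when omitted)
#' @return a [NucleiSegmentation-class]
#' @export
segmentNuclei <- function(image, params = segmenterParams(), denoiser = NULL,
                          codebook = NULL, stains = NULL) {
  p <- utils::modifyList(segmenterParams(), params %||% list())
  if (length(dim(image)) == 3L) {
    od <- rgbToOD(image, p$background)
    fg <- sqrt(rowSums(matrix(od, ncol = 3L)^2)) > p$odThreshold
    if (sum(fg) < 2L)   # pure background: nothing to segment
      return(.makeSegmentation(matrix(0L, dim(image)[1], dim(image)[2])))
    if (is.null(stains))
      stains <- estimateStainMatrix(image, p$alphaPercentile, p$odThreshold,
                                    p$background)
    hema <- separateHematoxylin(image, stains, p$background)
  } else {
    hema <- image
  }
  removed <- NULL
  if (!is.null(denoiser)) {
    if (is.null(codebook))
      stop("a codebook is required to apply the denoiser", call. = FALSE)
    if (codebook@patchSize != denoiser@patchSize ||
        codebookSize(codebook) != denoiser@nCodes)
      stop("codebook configuration does not match the denoiser model",
           call. = FALSE)
    grid <- tileImage(hema, denoiser@tileSize)
    hist <- encodeTiles(hema, grid, codebook)
    cls <- classifyTiles(denoiser, hist)
    removed <- removeBackground(matrix(1, nrow(hema), ncol(hema)), grid,
                                cls$label, fillValue = 0) == 0
    # blank at the background hematoxylin level: removed tiles become
    # featureless without introducing artificial step edges
    bgLevel <- stats::quantile(hema, p$bgQuantile, names = FALSE)
    hema <- removeBackground(hema, grid, cls$label, fillValue = bgLevel)
  }
  sm <- if (p$smoothSigma > 0) EBImage::gblur(hema, sigma = p$smoothSigma)
        else hema
  frst <- fastRadialSymmetry(max(sm) - sm, p$radii, p$alpha,
                             p$gradientThreshold)
  # aggregate-map smoothing merges secondary maxima inside large nuclei
  if (p$mapSigma > 0) {
    sc <- attr(frst, "scale")
    frst <- EBImage::gblur(frst, sigma = p$mapSigma)
    attr(frst, "scale") <- sc
  }
  markers <- detectMarkers(frst, p$minDistance, p$relThreshold)
  if (!is.null(removed) && nrow(markers) > 0L)
    markers <- markers[!removed[markers], , drop = FALSE]
  seg <- markerWatershed(sm, markers, p$bgQuantile)
  # duplicate markers inside one large nucleus split it in two; merging
  # adjacent regions whose union is rounder undoes exactly those splits
  seg <- .makeSegmentation(.mergeSplitRegions(labelMask(seg),
                                              maxArea = p$areaRange[2]))
  filterRegions(seg, p$areaRange, p$minRoundness, p$minSolidity)
}
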