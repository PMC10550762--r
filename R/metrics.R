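#' Dice similarity of two binary masks
#'
#' 2 |A intersect B| / (|A| + |B|), symmetric, in [0, 1].
#'
#' @param a,b binary (logical or 0/1) masks of identical shape
#' @return Dice score
#' @export
diceScore <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks must have identical shape", call. = FALSE)
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a & b) / (sa + sb)
}

#' Match detected nuclei to ground truth and score detection
#'
#' A detection counts as a true positive when its mask intersects a
#' ground-truth nucleus (>= 1 shared pixel) and the centroid distance is
#' below `maxDist` (12 px by default). Matching is one-to-one and greedy
#' in ascending centroid distance. Unmatched detections are false
#' positives, unmatched ground-truth nuclei false negatives, and
#' F1 = TP / (TP + (FP + FN) / 2).
#'
#' @param detected,gt [NucleiSegmentation-class] objects in the same frame
#' @param maxDist centroid matching radius in pixels
#' @return list of class `matchReport`: tp, fp, fn, f1 and a `pairs`
#'   data.frame (detected, gt, distance)
#' @export
matchNuclei <- function(detected, gt, maxDist = 12) {
  stopifnot(is(detected, "NucleiSegmentation"), is(gt, "NucleiSegmentation"))
  if (!all(dim(detected@labels) == dim(gt@labels)))
    stop("segmentations are not in the same image frame", call. = FALSE)
  nd <- nucleiCount(detected); ng <- nucleiCount(gt)
  pairs <- data.frame(detected = integer(0), gt = integer(0),
                      distance = numeric(0))
  if (nd > 0L && ng > 0L) {
    cd <- centroids(detected); cg <- centroids(gt)
    dist <- sqrt(outer(cd[, 1], cg[, 1], "-")^2 +
                 outer(cd[, 2], cg[, 2], "-")^2)
    cand <- which(dist < maxDist, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      overlap <- vapply(seq_len(nrow(cand)), function(i) {
        sum(detected@labels == cand[i, 1] & gt@labels == cand[i, 2]) > 0L
      }, logical(1))
      cand <- cand[overlap, , drop = FALSE]
    }
    if (nrow(cand) > 0L) {
      d <- dist[cand]
      o <- order(d, cand[, 1], cand[, 2])
      usedD <- logical(nd); usedG <- logical(ng)
      for (i in o) {
        di <- cand[i, 1]; gi <- cand[i, 2]
        if (usedD[di] || usedG[gi]) next
        usedD[di] <- TRUE; usedG[gi] <- TRUE
        pairs <- rbind(pairs, data.frame(detected = di, gt = gi,
                                         distance = dist[di, gi]))
      }
    }
  }
  tp <- nrow(pairs); fp <- nd - tp; fn <- ng - tp
  f1 <- if (tp + fp + fn == 0) NaN else tp / (tp + 0.5 * (fp + fn))
  structure(list(tp = tp, fp = fp, fn = fn, f1 = f1, pairs = pairs),
            class = "matchReport")
}

#' @export
print.matchReport <- function(x, ...) {
  cat(sprintf("matchReport: TP %d, FP %d, FN %d, F1 %.3f\n",
              x$tp, x$fp, x$fn, x$f1))
  invisible(x)
}

#' Pearson correlation between annotated and detected nuclei counts
#'
#' @param annotated,detected numeric vectors of per-image counts
#'   (at least 3 pairs, neither constant)
#' @return Pearson product-moment correlation
#' @export
countCorrelation <- function(annotated, detected) {
  if (length(annotated) != length(detected) || length(annotated) < 3L)
    stop("at least 3 (annotated, detected) pairs are required", call. = FALSE)
  if (stats::sd(annotated) == 0 || stats::sd(detected) == 0)
    stop("correlation is undefined for a constant count vector",
         call. = FALSE)
  stats::cor(annotated, detected)
}

#' Build a segmentation object from an instance mask
#'
#' Wraps a ground-truth label mask (integers 1..n over background 0)
#' into a [NucleiSegmentation-class] so it can be fed to [matchNuclei()]
#' and [diceScore()].
#'
#' @param mask H x W integer instance mask
#' @return a [NucleiSegmentation-class]
#' @export
segmentationFromMask <- function(mask) {
  storage.mode(mask) <- "integer"
  .makeSegmentation(mask)
}
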