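# shared fixture builders; everything is generated in code

# forward Beer-Lambert renderer: the independent oracle for the stain module
renderFromConcentrations <- function(cH, cE, stains = defaultStainMatrix(),
                                     background = 255, quantize = FALSE) {
  H <- nrow(cH); W <- ncol(cH)
  od <- stains %*% rbind(as.vector(cH), as.vector(cE))
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- matrix(background * exp(-od[ch, ]), H, W)
  if (quantize) img <- round(pmin(pmax(img, 0), background))
  img
}

# binary disk mask, integer-labeled per center
diskMask <- function(H, W, centers, radius) {
  m <- matrix(0L, H, W)
  ri <- matrix(rep(seq_len(H), W), H, W)
  ci <- matrix(rep(seq_len(W), each = H), H, W)
  for (k in seq_len(nrow(centers)))
    m[(ri - centers[k, 1])^2 + (ci - centers[k, 2])^2 <= radius^2] <- k
  m
}

# hand-built m = 2 noiselet matrix from the recursion (independent oracle)
handNoiselet2 <- function() {
  matrix(c(1 - 1i, 1 + 1i, 1 + 1i, 1 - 1i), 2, 2, byrow = TRUE) / 2
}

# small clean field shared by segmenter tests (default nucleus sizes)
cleanSample <- function(seed = 7, n = 8, size = 320) {
  generateSample(syntheticParams(imageSize = c(size, size), nNuclei = n,
                                 background = "flat", seed = seed))
}
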