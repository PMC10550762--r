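# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.isPow2 <- function(m) {
  length(m) == 1L && is.finite(m) && m >= 1 && m == as.integer(m) &&
    bitwAnd(as.integer(m), as.integer(m) - 1L) == 0L
}

.assertScalarInt <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x))
    stop(name, " must be a single integer, got ", deparse(x), call. = FALSE)
  as.integer(x)
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# excess kurtosis (fourth standardized moment minus 3)
.excessKurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

# Shannon entropy (nats) of a histogram of x over `bins` equal-width bins
.histEntropy <- function(x, bins = 32L, range = NULL) {
  range <- range %||% range(x)
  h <- tabulate(pmin(bins, pmax(1L, findInterval(
    x, seq(range[1], range[2], length.out = bins + 1L),
    rightmost.closed = TRUE))), bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}
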