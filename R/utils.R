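#' @importFrom stats rnorm runif rbinom qt pt pf sd var cor quantile qnorm
#'   pnorm mad coef lm fft mvfft nextn approx splinefun cooks.distance
#'   cov qlogis plogis p.adjust friedman.test rgamma
#' @importFrom methods new validObject is slot
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Deterministic child seed derived from a parent seed; kept below 2^31.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647)
}

## numpy-style gradient: central differences inside, one-sided at edges.
numGradient <- function(y, dx = 1) {
  n <- length(y)
  if (n < 2L) stop("gradient needs at least 2 points")
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / dx
  g[n] <- (y[n] - y[n - 1]) / dx
  if (n > 2L) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dx)
  g
}

## log(mean(exp(x))) without overflow
logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

## angular distance between unit vectors (rows of a) and a single unit vector b
angDist <- function(a, b) {
  d <- as.vector(a %*% b)
  acos(pmin(1, pmax(-1, d)))
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
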