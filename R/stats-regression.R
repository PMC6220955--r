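## Robust simple regression (IRLS with bisquare weights), Cook's-distance
## outlier screening, BCa bootstrap confidence intervals and
## Bonferroni-adjusted slope-difference tests.

#' Fast bisquare IRLS fit of a simple regression
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, robust scale = MAD/0.6745), the classical
#' robust-regression default. Starts from ordinary least squares.
#'
#' @param x,y numeric vectors
#' @param tune bisquare tuning constant (default 4.685)
#' @param maxIter,tol iteration controls
#' @return list with beta0, beta1, weights, sigma, iterations
#' @export
bisquareFit <- function(x, y, tune = 4.685, maxIter = 50L, tol = 1e-6) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0) stop("zero variance in x")
  mx <- mean(x); my <- mean(y)
  b1 <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  b0 <- my - b1 * mx
  w <- rep(1, n)
  s <- 0
  half <- 3:n
  for (it in seq_len(maxIter)) {
    r <- y - b0 - b1 * x
    ## robust scale from the n-2 largest absolute residuals (uncentred),
    ## so tied grid-valued residuals cannot collapse the scale
    rs <- sort.int(abs(r), method = "quick")
    s <- stats::median(rs[half]) / 0.6745
    if (s < 1e-10 * max(rs[n], 1)) { w <- rep(1, n); break }  # perfect fit
    w <- 1 - (r / (tune * s))^2
    w[w < 0] <- 0
    w <- w * w
    sw <- sum(w)
    if (sw < .Machine$double.eps) break
    mxw <- sum(w * x) / sw
    myw <- sum(w * y) / sw
    dx <- x - mxw
    denom <- sum(w * dx * dx)
    if (denom < 1e-14) break
    b1New <- sum(w * dx * (y - myw)) / denom
    b0New <- myw - b1New * mxw
    delta <- max(abs(b1New - b1), abs(b0New - b0))
    b1 <- b1New; b0 <- b0New
    if (delta < tol) break
  }
  list(beta0 = b0, beta1 = b1, weights = w, sigma = s, iterations = it)
}

#' Cook's-distance outlier screening
#'
#' Computes Cook's distances from an ordinary least-squares fit and flags
#' points with distance above the threshold (default 4/n).
#'
#' @param x,y numeric vectors
#' @param threshold Cook's distance cutoff; default `4 / length(x)`
#' @return integer indices of the flagged points
#' @export
cooksOutliers <- function(x, y, threshold = 4 / length(x)) {
  fit <- lm(y ~ x)
  which(as.vector(cooks.distance(fit)) > threshold)
}

#' Robust linear regression with outlier screening
#'
#' Removes gross outliers by Cook's distance (computed from an ordinary
#' fit), then fits the remaining points by bisquare IRLS. Goodness of fit
#' and the F-test against a constant model are computed from the final
#' robust weights. Optionally attaches BCa bootstrap confidence intervals
#' for both coefficients.
#'
#' @param x,y numeric vectors (one value per subject)
#' @param removeOutliers apply the Cook's-distance screen (default TRUE)
#' @param cooksThreshold cutoff, default 4/n
#' @param nBoot bootstrap resamples for the coefficient CIs (0 = none)
#' @param level CI confidence level (default 0.95)
#' @param seed integer RNG seed for the bootstrap
#' @return a [RegressionFit-class]
#' @export
robustFit <- function(x, y, removeOutliers = TRUE,
                      cooksThreshold = 4 / length(x), nBoot = 0L,
                      level = 0.95, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (sd(x) == 0) stop("zero variance in x")
  out <- integer(0)
  if (removeOutliers) {
    out <- cooksOutliers(x, y, cooksThreshold)
    if (length(x) - length(out) < 5)
      stop("fewer than 5 points remain after outlier removal")
  }
  keep <- setdiff(seq_along(x), out)
  xs <- x[keep]; ys <- y[keep]
  fit <- bisquareFit(xs, ys)
  w <- fit$weights
  pred <- fit$beta0 + fit$beta1 * xs
  sw <- sum(w)
  ybarw <- sum(w * ys) / sw
  ssRes <- sum(w * (ys - pred)^2)
  ssTot <- sum(w * (ys - ybarw)^2)
  r2 <- if (is.finite(ssTot) && ssTot > 0) 1 - ssRes / ssTot else NA_real_
  dfErr <- length(xs) - 2L
  Fv <- if (ssRes > 0) ((ssTot - ssRes) / 1) / (ssRes / dfErr) else Inf
  pv <- pf(Fv, 1, dfErr, lower.tail = FALSE)
  ci <- data.frame(coef = character(0), lower = numeric(0),
                   upper = numeric(0), level = numeric(0))
  if (nBoot > 0) {
    dat <- cbind(xs, ys)
    ci0 <- bcaBootstrapCI(function(d) bisquareFit(d[, 1], d[, 2])$beta0,
                          dat, nBoot = nBoot, level = level,
                          seed = childSeed(seed, 1L))
    ci1 <- bcaBootstrapCI(function(d) bisquareFit(d[, 1], d[, 2])$beta1,
                          dat, nBoot = nBoot, level = level,
                          seed = childSeed(seed, 2L))
    ci <- data.frame(coef = c("beta0", "beta1"),
                     lower = c(ci0$lower, ci1$lower),
                     upper = c(ci0$upper, ci1$upper),
                     level = level)
  }
  new("RegressionFit", beta0 = fit$beta0, beta1 = fit$beta1, r2 = r2,
      fStat = Fv, pValue = pv, ci = ci,
      outliersRemoved = as.integer(out), n = length(xs),
      weights = w)
}

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "RegressionFit: beta0 = %.3f, beta1 = %.3f, R2 = %.3f, F = %.3f (p = %.4g), n = %d\n",
    object@beta0, object@beta1, object@r2, object@fStat, object@pValue,
    object@n))
  if (length(object@outliersRemoved))
    cat("  outliers removed:", paste(object@outliersRemoved,
                                     collapse = ", "), "\n")
  if (nrow(object@ci)) {
    for (i in seq_len(nrow(object@ci)))
      cat(sprintf("  %s %g%% CI [%.3f, %.3f]\n", object@ci$coef[i],
                  100 * object@ci$level[i], object@ci$lower[i],
                  object@ci$upper[i]))
  }
})

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement, computes the statistic on
#' each resample, and forms the BCa interval: the bias correction z0 is
#' the normal quantile of the proportion of bootstrap statistics below the
#' point estimate, the acceleration is estimated from the jackknife
#' skewness, and the interval endpoints are the correspondingly adjusted
#' bootstrap percentiles.
#'
#' @param statisticFn function of a data matrix/data.frame returning a
#'   scalar
#' @param data matrix or data.frame; rows are resampled (subjects)
#' @param nBoot number of bootstrap resamples (default 10000)
#' @param level confidence level (default 0.95)
#' @param seed integer RNG seed
#' @return list with estimate, lower, upper, z0, accel, level, and
#'   `degenerate` (TRUE when the bootstrap distribution is a point mass)
#' @export
bcaBootstrapCI <- function(statisticFn, data, nBoot = 10000L,
                           level = 0.95, seed = 1L) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(n >= 3)
  est <- statisticFn(data)
  safeStat <- function(d)  # degenerate resamples contribute nothing
    tryCatch(statisticFn(d), error = function(e) NA_real_)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      safeStat(data[idx, , drop = FALSE])
    }, 0)
  })
  boots <- boots[is.finite(boots)]
  if (length(boots) == 0L) {
    warning("all bootstrap resamples failed")
    return(list(estimate = est, lower = NA_real_, upper = NA_real_,
                z0 = NA_real_, accel = NA_real_, level = level,
                degenerate = TRUE))
  }
  if (length(unique(boots)) == 1L) {
    warning("degenerate bootstrap distribution (point mass)")
    return(list(estimate = est, lower = boots[1], upper = boots[1],
                z0 = 0, accel = 0, level = level, degenerate = TRUE))
  }
  z0 <- qnorm((sum(boots < est) + 0.5 * sum(boots == est)) /
              length(boots))
  jack <- vapply(seq_len(n), function(i)
    safeStat(data[-i, , drop = FALSE]), 0)
  jack <- jack[is.finite(jack)]
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den > 0) num / den else 0
  alpha <- (1 - level) / 2
  adjusted <- function(q) {
    zq <- qnorm(q)
    pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  }
  lims <- quantile(boots, c(adjusted(alpha), adjusted(1 - alpha)),
                   names = FALSE, type = 7)
  list(estimate = est, lower = lims[1], upper = lims[2], z0 = z0,
       accel = a, level = level, degenerate = FALSE)
}

#' Bootstrap test for a slope difference between two conditions
#'
#' Resamples subjects (paired across conditions), recomputes the robust
#' slope difference on every resample and forms its BCa interval at a
#' Bonferroni-adjusted confidence level (default `1 - 0.05 / 3` for three
#' pairwise comparisons). The null hypothesis of equal slopes is rejected
#' when the interval excludes zero.
#'
#' @param xA,yA,xB,yB per-subject predictor/outcome pairs of the two
#'   conditions, aligned by subject
#' @param nBoot bootstrap resamples (default 10000)
#' @param level confidence level (default `1 - 0.05 / 3`)
#' @param seed integer RNG seed
#' @return list with deltaBeta1, lower, upper, level, reject
#' @export
slopeDifferenceTest <- function(xA, yA, xB, yB, nBoot = 10000L,
                                level = 1 - 0.05 / 3, seed = 1L) {
  n <- length(xA)
  stopifnot(length(yA) == n, length(xB) == n, length(yB) == n)
  dat <- cbind(xA, yA, xB, yB)
  statFn <- function(d)
    bisquareFit(d[, 1], d[, 2])$beta1 - bisquareFit(d[, 3], d[, 4])$beta1
  ci <- bcaBootstrapCI(statFn, dat, nBoot = nBoot, level = level,
                       seed = seed)
  list(deltaBeta1 = ci$estimate, lower = ci$lower, upper = ci$upper,
       level = level, reject = ci$lower > 0 || ci$upper < 0)
}
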