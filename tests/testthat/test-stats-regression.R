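test_that("bisquare IRLS matches the reference implementation", {
  skip_if_not_installed("MASS")
  for (s in 1:5) {
    xy <- withSeed(s, {
      x <- rnorm(17)
      y <- 0.3 + 0.8 * x + rnorm(17, 0, 0.3)
      ## one moderate outlier in some replicates
      if (s %% 2 == 0) y[1] <- y[1] + 3
      list(x = x, y = y)
    })
    fit <- bisquareFit(xy$x, xy$y)
    ref <- MASS::rlm(y ~ x, data = xy, psi = MASS::psi.bisquare,
                     c = 4.685, maxit = 100)
    expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 0.02)
    expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 0.02)
  }
})

test_that("robust fits resist gross outliers where OLS fails", {
  xy <- withSeed(3, {
    x <- rnorm(17)
    y <- 0.3 + 0.8 * x + rnorm(17, 0, 0.2)
    list(x = x, y = y)
  })
  ## clean data: bisquare equals OLS essentially exactly
  clean <- bisquareFit(xy$x, 1 + 2 * xy$x)
  expect_equal(clean$beta1, 2, tolerance = 1e-8)
  y3 <- xy$y
  y3[1] <- y3[1] + 8
  rob <- bisquareFit(xy$x, y3)
  ols <- unname(coef(lm(y3 ~ xy$x))[2])
  expect_lt(abs(rob$beta1 - 0.8), 0.05)
  expect_gt(abs(ols - 0.8), 0.2)
  ## Cook's screening removes the planted point
  rf <- robustFit(xy$x, y3)
  expect_true(1L %in% rf@outliersRemoved)
  ## standardized inputs give a near-zero intercept
  zf <- bisquareFit(scale(xy$x)[, 1], scale(xy$y)[, 1])
  expect_lt(abs(zf$beta0), 0.05)
  expect_error(robustFit(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("grid-valued data with tied residuals keep finite weights", {
  ## half the points exactly on a line, the rest offset: the uncentred
  ## robust scale must not collapse
  x <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5)
  y <- x
  y[c(2, 4, 6, 8, 10)] <- y[c(2, 4, 6, 8, 10)] + 0.45
  fit <- bisquareFit(x, y)
  expect_true(all(is.finite(fit$weights)))
  expect_gt(sum(fit$weights), 1)
  rf <- robustFit(x, y, removeOutliers = FALSE)
  expect_true(is.finite(rf@fStat))
})

test_that("BCa intervals match the boot package on the same statistic", {
  skip_if_not_installed("boot")
  xy <- withSeed(9, cbind(rnorm(17), 0.3 + 0.8 * rnorm(17)))
  xy[, 2] <- 0.3 + 0.8 * xy[, 1] + withSeed(10, rnorm(17, 0, 0.25))
  statFn <- function(d) bisquareFit(d[, 1], d[, 2])$beta1
  ci <- bcaBootstrapCI(statFn, xy, nBoot = 4000, seed = 21)
  bt <- withSeed(21, boot::boot(xy, function(d, i) statFn(d[i, ]),
                                R = 4000))
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(ci$lower, ref[1], tolerance = 0.05)
  expect_equal(ci$upper, ref[2], tolerance = 0.05)
})

test_that("BCa reduces to the percentile interval for symmetric
           statistics", {
  dat <- withSeed(4, matrix(rnorm(40), ncol = 1))
  statFn <- function(d) mean(d[, 1])
  ci <- bcaBootstrapCI(statFn, dat, nBoot = 6000, seed = 2)
  expect_lt(abs(ci$z0), 0.08)
  expect_lt(abs(ci$accel), 0.05)
  boots <- withSeed(2, vapply(1:6000, function(b) {
    idx <- sample.int(40, 40, replace = TRUE)
    statFn(dat[idx, , drop = FALSE])
  }, 0))
  perc <- quantile(boots, c(0.025, 0.975), names = FALSE)
  expect_equal(ci$lower, perc[1], tolerance = 0.05)
  expect_equal(ci$upper, perc[2], tolerance = 0.05)
  ## endpoints widen monotonically with the confidence level
  ci99 <- bcaBootstrapCI(statFn, dat, nBoot = 6000, level = 0.99,
                         seed = 2)
  expect_lt(ci99$lower, ci$lower)
  expect_gt(ci99$upper, ci$upper)
})

test_that("degenerate bootstrap distributions are flagged", {
  dat <- matrix(rep(1, 10), ncol = 1)
  expect_warning(
    ci <- bcaBootstrapCI(function(d) mean(d[, 1]), dat, nBoot = 50,
                         seed = 1),
    "degenerate")
  expect_true(ci$degenerate)
})

test_that("slope differences between equal-slope conditions include
           zero", {
  hits <- 0
  nRep <- 20
  for (r in seq_len(nRep)) {
    ab <- withSeed(40 + r, {
      x1 <- rnorm(17); x2 <- rnorm(17)
      list(x1 = x1, y1 = 0.8 * x1 + rnorm(17, 0, 0.4),
           x2 = x2, y2 = 0.8 * x2 + rnorm(17, 0, 0.4))
    })
    res <- slopeDifferenceTest(ab$x1, ab$y1, ab$x2, ab$y2, nBoot = 400,
                               seed = r)
    if (!res$reject) hits <- hits + 1
  }
  expect_gte(hits / nRep, 1 - 0.05 / 3 - 0.15)
})
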