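## Repeated-measures ANOVA (fully within-subject, balanced) with
## Greenhouse-Geisser sphericity correction and partial omega squared.

## orthonormal contrast matrix (k x (k-1)), columns orthogonal to 1
orthonormalContrasts <- function(k) {
  if (k < 2) stop("factor needs at least 2 levels")
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject, balanced ANOVA over any number of crossed
#' factors. For each effect, per-subject contrast scores are formed from
#' orthonormal factor contrasts; F is the ratio of the mean squared
#' contrast mean to the subject-by-contrast interaction. The
#' Greenhouse-Geisser epsilon is estimated from the covariance of the
#' contrast scores and applied to the degrees of freedom. Effect sizes are
#' reported as partial omega squared,
#' `df_eff (F - 1) / (df_eff (F - 1) + df_eff + df_err + 1)`,
#' truncated at zero.
#'
#' @param data long-format data.frame with columns `subject`, `value` and
#'   one column per factor
#' @param within character vector of factor column names
#' @return an [AnovaResult-class]
#' @export
rmAnovaGG <- function(data, within) {
  stopifnot(all(c("subject", "value", within) %in% names(data)))
  facs <- lapply(within, function(f) factor(data[[f]]))
  names(facs) <- within
  levelsList <- lapply(facs, levels)
  k <- vapply(levelsList, length, 0L)
  subjects <- factor(data$subject)
  n <- nlevels(subjects)
  nCells <- prod(k)
  ## cell matrix Y: subjects x cells, cells ordered with the first factor
  ## varying slowest
  cellIdx <- 1L
  mult <- 1L
  for (f in rev(seq_along(within))) {
    cellIdx <- cellIdx + (as.integer(facs[[f]]) - 1L) * mult
    mult <- mult * k[f]
  }
  if (anyDuplicated(cbind(as.integer(subjects), cellIdx)))
    stop("duplicate subject x cell observations; design must be complete ",
         "with one value per cell")
  if (length(cellIdx) != n * nCells)
    stop("missing cells: design must be balanced and complete")
  Y <- matrix(NA_real_, n, nCells)
  Y[cbind(as.integer(subjects), cellIdx)] <- data$value

  effects <- unlist(lapply(seq_along(within), function(ord)
    utils::combn(seq_along(within), ord, simplify = FALSE)),
    recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    M <- matrix(1, 1, 1)
    for (f in seq_along(within)) {
      Mf <- if (f %in% eff) orthonormalContrasts(k[f])
            else matrix(1 / k[f], k[f], 1)
      M <- kronecker(M, Mf)
    }
    Z <- Y %*% M
    q <- ncol(Z)
    zBar <- colMeans(Z)
    ssEff <- n * sum(zBar^2)
    ssErr <- sum(sweep(Z, 2, zBar)^2)
    dfEff <- q
    dfErr <- q * (n - 1)
    Fval <- (ssEff / dfEff) / (ssErr / dfErr)
    S <- cov(Z)
    eps <- if (q == 1) 1 else sum(diag(S))^2 / (q * sum(S * S))
    omega <- dfEff * (Fval - 1) / (dfEff * (Fval - 1) + dfEff + dfErr + 1)
    data.frame(
      effect = paste(within[eff], collapse = ":"),
      dfEff = dfEff, dfErr = dfErr, F = Fval,
      p = pf(Fval, dfEff, dfErr, lower.tail = FALSE),
      epsilonGG = eps,
      pGG = pf(Fval, dfEff * eps, dfErr * eps, lower.tail = FALSE),
      omegaP2 = max(0, omega),
      omegaTruncated = omega < 0)
  })
  new("AnovaResult", table = do.call(rbind, rows), nSubjects = as.integer(n))
}

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("Repeated-measures ANOVA (n = %d):\n", object@nSubjects))
  tab <- object@table
  tab$F <- round(tab$F, 3)
  tab$p <- signif(tab$p, 3)
  tab$pGG <- signif(tab$pGG, 3)
  tab$epsilonGG <- round(tab$epsilonGG, 3)
  tab$omegaP2 <- round(tab$omegaP2, 3)
  print(tab, row.names = FALSE)
})
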