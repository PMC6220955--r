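## Friedman test, logit transform and Holm-Bonferroni correction.

#' Friedman rank test across repeated conditions
#'
#' Rank-based test for equal condition distributions in a complete block
#' design (subjects x conditions), with midrank tie handling and the tie
#' correction of the classical statistic (via [stats::friedman.test()]).
#' With all-tied rows the statistic is 0 and p = 1.
#'
#' @param values subjects x conditions matrix
#' @return list with statistic (chi-square), df (k - 1) and p.value
#' @export
friedmanTest <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("complete block design required (no NA)")
  ## all-constant rows make the classical statistic 0/0; resolve to 0
  if (all(apply(values, 1, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, df = ncol(values) - 1L, p.value = 1))
  ft <- friedman.test(values)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value)
}

#' Logit transform of a proportion
#'
#' `log(p / (1 - p))` with clipping at `1/(2 nTrials)` from both bounds
#' (or machine epsilon when no trial count is given) so that perfect
#' scores remain finite.
#'
#' @param p proportion(s) in [0, 1]
#' @param nTrials number of trials behind each proportion (optional)
#' @return logit value(s)
#' @export
logitTransform <- function(p, nTrials = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  eps <- if (is.null(nTrials)) .Machine$double.eps else 1 / (2 * nTrials)
  qlogis(clamp(p, eps, 1 - eps))
}

#' Holm-Bonferroni step-down correction
#'
#' @param pValues vector of raw p-values
#' @param alpha family-wise error level (default 0.05)
#' @return data.frame with p, pAdjusted (monotone after sorting), reject
#' @export
holmBonferroni <- function(pValues, alpha = 0.05) {
  adj <- p.adjust(pValues, method = "holm")
  data.frame(p = pValues, pAdjusted = adj, reject = adj < alpha)
}
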