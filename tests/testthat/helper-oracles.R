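# Independent oracle: deterministic nested quadrature of the same
# mixture-of-g marginal likelihoods that jzsAnovaBF integrates by MC.
quadratureBF <- function(data, within, rFixed = 0.5, rRandom = 1) {
  facs <- lapply(within, function(f) factor(data[[f]]))
  names(facs) <- within
  n <- nlevels(factor(data$subject))
  yc <- data$value - mean(data$value)
  yty <- sum(yc^2)
  N <- nrow(data)
  Xs <- alphakit:::orthonormalContrasts(n)[
    as.integer(factor(data$subject)), , drop = FALSE]
  Xa <- alphakit:::.effectDesign(facs, 1L)
  summ <- alphakit:::.groupSummaries(list(Xs, Xa), yc)
  condML <- function(gs, ga) {
    ld <- sum(log1p(gs * summ[[1]]$lambda)) +
      sum(log1p(ga * summ[[2]]$lambda))
    qd <- sum(summ[[1]]$b^2 * gs / (1 + gs * summ[[1]]$lambda)) +
      sum(summ[[2]]$b^2 * ga / (1 + ga * summ[[2]]$lambda))
    exp(-0.5 * ld - ((N - 1) / 2) * (log(yty - qd) - log(yty)))
  }
  dig <- function(g, r)
    (r^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
  m1 <- integrate(Vectorize(function(gs) {
    dig(gs, rRandom) * integrate(Vectorize(function(ga)
      condML(gs, ga) * dig(ga, rFixed)), 0, Inf, rel.tol = 1e-8)$value
  }), 0, Inf, rel.tol = 1e-7)$value
  m0 <- integrate(Vectorize(function(gs)
    dig(gs, rRandom) * condML(gs, 1e-300)), 0, Inf,
    rel.tol = 1e-8)$value
  m1 / m0
}

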