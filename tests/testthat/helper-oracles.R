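# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the pmf is evaluated through the
# rising-factorial product form, and moments come from brute-force
# enumeration of the discrete simplex.

# rising-factorial (Pochhammer) form of the EFDM pmf, evaluated term by term
efdmDirectLogPmf <- function(y, alpha, tau, p) {
  n <- sum(y)
  lrf <- function(a, k) lgamma(a + k) - lgamma(a)
  ap <- sum(alpha)
  base <- lgamma(n + 1) - sum(lgamma(y + 1)) + sum(lrf(alpha, y))
  s <- 0
  for (r in seq_along(y)) {
    if (p[r] == 0) next
    s <- s + p[r] * exp(-lrf(ap + tau[r], n) +
                          lrf(alpha[r] + tau[r], y[r]) - lrf(alpha[r], y[r]))
  }
  base + log(s)
}

# exact moments by enumerating the pmf over the discrete simplex
enumMoments <- function(params, n) {
  D <- length(params@alpha)
  g <- simplexGrid(D, n)
  pr <- defdm(g, params)
  m <- colSums(g * pr)
  V <- t(g) %*% (g * pr) - tcrossprod(m)
  list(mean = m, cov = V, total = sum(pr))
}

# interclass/intraclass correlations extracted from the n = 2 enumeration:
# for a sum of two exchangeable single-read indicator vectors,
# Cov(Y) = 2 M(mu) + 2 Cov_between, so the between-draw covariance (and the
# class correlations) follow directly from the count covariance.
enumClassCorr <- function(params) {
  em <- enumMoments(params, 2)
  mu <- em$mean / 2
  between <- em$cov / 2 - (diag(mu) - tcrossprod(mu))
  denom <- tcrossprod(sqrt(mu * (1 - mu)))
  corr <- between / denom
  list(intra = diag(corr), inter = corr)
}

# random valid natural parameter set
randomParams <- function(D, allowZeroWeight = FALSE) {
  alpha <- runif(D, 0.3, 4)
  tau <- runif(D, 0.3, 6)
  p <- rgamma(D, 1.5)
  p <- p / sum(p)
  while (max(p) >= 1) {
    p <- rgamma(D, 1.5)
    p <- p / sum(p)
  }
  if (allowZeroWeight && D > 2) {
    p[1] <- 0
    p <- p / sum(p)
  }
  efdmParams(alpha, tau, p)
}

# parameter set with a strictly positive interclass correlation (found by
# search, frozen; verified against the n = 2 enumeration oracle)
positiveDependenceParams <- function() {
  efdmParams(alpha = c(0.323, 1.451, 1.740, 1.171),
             tau = c(5.355, 47.354, 3.158, 50.670),
             p = c(0.1705, 0.3744, 0.0059, 0.4492))
}

# small fitted object on a tiny dataset, shared by evaluation tests
tinyFit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateScenario(caseIVScenario(), seed = 42, N = 80,
                              readsMean = 40)
      fit <- fitEFDMReg(sim$data, "dm",
                        mcmc = mcmcConfig(chains = 1, warmup = 800,
                                          iter = 600, thin = 3, seed = 7))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})
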