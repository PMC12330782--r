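#' Simulation scenario description
#'
#' A scenario bundles everything needed to draw replicated datasets: the
#' number of taxa and covariates, sample size, the Poisson mean of the
#' per-sample read totals (truncated at 1; a sample with zero reads is
#' undefined in these models), the true coefficient matrix and the global
#' response-family parameters.
#'
#' @param name scenario label.
#' @param family generating family.
#' @param coeffs (D-1) x (K+1) true coefficient matrix (baseline row
#'   omitted; baseline is the last taxon).
#' @param alphaPlus,p,wtilde global truth (as required by the family).
#' @param N number of samples.
#' @param readsMean Poisson mean of the read totals.
#' @return list of class `efdmScenario`.
#' @export
efdmScenario <- function(name, family = c("efdm", "fdm", "dm", "multinomial"),
                         coeffs, alphaPlus = NULL, p = NULL, wtilde = NULL,
                         N = 500, readsMean = 100) {
  family <- match.arg(family)
  coeffs <- as.matrix(coeffs)
  D <- nrow(coeffs) + 1
  structure(list(name = name, family = family, coeffs = coeffs,
                 D = D, K = ncol(coeffs) - 1,
                 alphaPlus = alphaPlus, p = p, wtilde = wtilde,
                 N = as.integer(N), readsMean = readsMean),
            class = "efdmScenario")
}

#' Variable-selection benchmark scenario (three taxa, nine covariates)
#'
#' N = 750 samples, read totals Poisson(50), nine i.i.d. standard-normal
#' covariates, three taxa with the last as baseline. Covariates 2, 4 and 6
#' affect both mean equations, covariate 3 mainly the first, and covariates
#' 1, 5, 7, 8, 9 are null. Global truth: alpha+ = 50, p = (0.25, 0.25, 0.5),
#' wtilde = (0.6, 0.8, 0.7).
#'
#' @return an `efdmScenario`.
#' @export
caseIScenario <- function() {
  coeffs <- rbind(
    c(-4.0, 0, -3, -3.0, 2.7, 0, 3.0, 0, 0, 0),
    c(1.5, 0, -2, 0.5, -3.0, 0, 2.5, 0, 0, 0))
  efdmScenario("caseI", "efdm", coeffs,
               alphaPlus = 50, p = c(0.25, 0.25, 0.5),
               wtilde = c(0.6, 0.8, 0.7), N = 750, readsMean = 50)
}

#' Parameter-recovery benchmark scenario (five taxa, one covariate)
#'
#' Five taxa, a single standard-normal covariate, intercepts
#' (-0.5, 1.5, 2, 3) and slopes (1.8, -2.5, -1, -2) against the fifth
#' (baseline) taxon; alpha+ = 50, p = (0.25, 0.3, 0.2, 0.1, 0.15), wtilde =
#' (0.6, 0.3, 0.9, 0.4, 0.35). Defaults N = 500 and Poisson(100) reads are
#' this package's choices for the study size.
#'
#' @param family generating family; "dm" gives the matching DM-generated
#'   variant (mean coefficients and precision only).
#' @return an `efdmScenario`.
#' @export
caseIVScenario <- function(family = c("efdm", "fdm", "dm", "multinomial")) {
  family <- match.arg(family)
  coeffs <- cbind(c(-0.5, 1.5, 2, 3), c(1.8, -2.5, -1, -2))
  efdmScenario("caseIV", family, coeffs,
               alphaPlus = 50, p = c(0.25, 0.3, 0.2, 0.1, 0.15),
               wtilde = c(0.6, 0.3, 0.9, 0.4, 0.35),
               N = 500, readsMean = 100)
}

# vectorized response sampling given per-sample means
.sampleFamily <- function(family, mu, totals, alphaPlus, p, wtilde) {
  N <- nrow(mu); D <- ncol(mu)
  pi <- switch(family,
    multinomial = mu,
    dm = {
      g <- matrix(rgamma(N * D, shape = alphaPlus * mu), N, D)
      g / rowSums(g)
    },
    fdm = ,
    efdm = {
      wt <- if (family == "fdm") rep(wtilde[1], D) else wtilde
      wtm <- matrix(wt, N, D, byrow = TRUE)
      pm <- matrix(p, N, D, byrow = TRUE)
      w <- wtm * pmin(1, mu / pm)
      S <- rowSums(pm * w)
      a <- alphaPlus * (mu - pm * w) / (1 - S)
      tau <- alphaPlus * w / (1 - w)
      comp <- sample.int(D, N, replace = TRUE, prob = p)
      conc <- a
      conc[cbind(seq_len(N), comp)] <- conc[cbind(seq_len(N), comp)] +
        tau[cbind(seq_len(N), comp)]
      g <- matrix(rgamma(N * D, shape = conc), N, D)
      g / rowSums(g)
    })
  out <- matrix(0L, N, D)
  for (i in seq_len(N)) out[i, ] <- rmultinom(1, totals[i], pi[i, ])
  out
}

#' Draw one replicated dataset from a scenario
#'
#' Covariates are i.i.d. standard normal, read totals are Poisson truncated
#' at 1, and counts follow the scenario's family with per-sample mean given
#' by the multinomial-logit link at the true coefficients.
#'
#' @param scenario an `efdmScenario`.
#' @param seed integer seed.
#' @param N,readsMean optional overrides of the scenario sizes.
#' @return list with `data` (an [EFDMExperiment-class]) and `truth` (named
#'   vector of true parameter values on the draw scale, plus the coefficient
#'   matrix and family).
#' @examples
#' sim <- simulateScenario(caseIVScenario(), seed = 7, N = 50)
#' dim(countMatrix(sim$data))
#' @export
simulateScenario <- function(scenario, seed, N = NULL, readsMean = NULL) {
  stopifnot(inherits(scenario, "efdmScenario"))
  set.seed(seed)
  N <- if (is.null(N)) scenario$N else as.integer(N)
  rm <- if (is.null(readsMean)) scenario$readsMean else readsMean
  D <- scenario$D; K <- scenario$K
  X <- cbind(1, matrix(rnorm(N * K), N, K))
  totals <- pmax(1L, rpois(N, rm))
  mu <- logitLinkMean(scenario$coeffs, X, baseline = D)
  counts <- .sampleFamily(scenario$family, mu, totals, scenario$alphaPlus,
                          scenario$p, scenario$wtilde)
  colnames(counts) <- paste0("taxon", seq_len(D))
  covs <- NULL
  if (K > 0) {
    covs <- as.data.frame(X[, -1, drop = FALSE])
    names(covs) <- paste0("x", seq_len(K))
  }
  data <- efdmExperiment(counts, covs, standardize = FALSE)
  truth <- .truthVector(scenario)
  list(data = data, truth = truth, scenario = scenario)
}

# named truth vector matching posterior draw column names
.truthVector <- function(scenario) {
  co <- scenario$coeffs
  v <- setNames(as.numeric(t(co)),
                as.vector(t(outer(seq_len(nrow(co)), seq_len(ncol(co)) - 1,
                                  function(r, k) paste0("beta[", r, ",", k, "]")))))
  if (scenario$family != "multinomial")
    v <- c(v, alphaPlus = scenario$alphaPlus)
  if (scenario$family %in% c("fdm", "efdm")) {
    v <- c(v, setNames(scenario$p, paste0("p[", seq_len(scenario$D), "]")))
    wt <- scenario$wtilde
    if (scenario$family == "fdm") v <- c(v, wtilde = wt[1])
    else v <- c(v, setNames(wt, paste0("wtilde[", seq_len(scenario$D), "]")))
  }
  v
}

#' Logistic-normal-multinomial generator (model mis-specification stressor)
#'
#' Latent additive-log-ratio coordinates are drawn from a normal with mean
#' `X B^T` and covariance `latentCov`, mapped through softmax (baseline last,
#' coordinate fixed at zero) and compounded with a multinomial. Positive
#' latent correlations translate into positive count correlations, which the
#' plain DM cannot represent.
#'
#' @param coeffs (D-1) x (K+1) coefficient matrix for the latent means.
#' @param latentCov (D-1) x (D-1) positive semidefinite covariance of the
#'   latent log-ratios.
#' @param N number of samples.
#' @param readsMean Poisson mean of read totals (truncated at 1).
#' @param seed integer seed.
#' @return list with `data` (an [EFDMExperiment-class]).
#' @export
simulateLogisticNormal <- function(coeffs, latentCov, N = 500,
                                   readsMean = 100, seed = 1) {
  coeffs <- as.matrix(coeffs)
  D <- nrow(coeffs) + 1
  K <- ncol(coeffs) - 1
  ev <- eigen(latentCov, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("latentCov must be positive semidefinite")
  set.seed(seed)
  X <- matrix(1, N, 1)
  if (K > 0) X <- cbind(X, matrix(rnorm(N * K), N, K))
  totals <- pmax(1L, rpois(N, readsMean))
  Z <- matrix(rnorm(N * (D - 1)), N, D - 1)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), D - 1)
  eta <- X %*% t(coeffs) + Z %*% t(L)
  eta <- cbind(eta, 0)
  ex <- exp(eta - apply(eta, 1, max))
  pi <- ex / rowSums(ex)
  counts <- matrix(0L, N, D)
  for (i in seq_len(N)) counts[i, ] <- rmultinom(1, totals[i], pi[i, ])
  colnames(counts) <- paste0("taxon", seq_len(D))
  covs <- NULL
  if (K > 0) {
    covs <- as.data.frame(X[, -1, drop = FALSE])
    names(covs) <- paste0("x", seq_len(K))
  }
  list(data = efdmExperiment(counts, covs, standardize = FALSE))
}

#' Dirichlet-multinomial data with structural excess zeros
#'
#' Draws DM-regression counts and superimposes structural zeros: with
#' probability `zeroProb` per sample-taxon cell (never the whole sample),
#' the latent composition coordinate is zeroed and the remainder
#' renormalized before the multinomial draw. Used to compare zero-handling
#' of the model families.
#'
#' @param scenario an `efdmScenario` with family "dm".
#' @param zeroProb per-cell structural-zero probability.
#' @param seed integer seed.
#' @param N,readsMean optional size overrides.
#' @return list with `data` and `truth` as in [simulateScenario()].
#' @export
simulateExcessZeros <- function(scenario, zeroProb = 0.3, seed = 1,
                                N = NULL, readsMean = NULL) {
  stopifnot(inherits(scenario, "efdmScenario"), scenario$family == "dm")
  set.seed(seed)
  N <- if (is.null(N)) scenario$N else as.integer(N)
  rm <- if (is.null(readsMean)) scenario$readsMean else readsMean
  D <- scenario$D; K <- scenario$K
  X <- cbind(1, matrix(rnorm(N * K), N, K))
  totals <- pmax(1L, rpois(N, rm))
  mu <- logitLinkMean(scenario$coeffs, X, baseline = D)
  g <- matrix(rgamma(N * D, shape = scenario$alphaPlus * mu), N, D)
  pi <- g / rowSums(g)
  drop <- matrix(runif(N * D) < zeroProb, N, D)
  # never zero out an entire sample
  allz <- rowSums(!drop) == 0
  drop[allz, 1] <- FALSE
  pi[drop] <- 0
  pi <- pi / rowSums(pi)
  counts <- matrix(0L, N, D)
  for (i in seq_len(N)) counts[i, ] <- rmultinom(1, totals[i], pi[i, ])
  colnames(counts) <- paste0("taxon", seq_len(D))
  covs <- as.data.frame(X[, -1, drop = FALSE])
  if (K > 0) names(covs) <- paste0("x", seq_len(K))
  sc <- scenario
  list(data = efdmExperiment(counts, if (K > 0) covs else NULL,
                             standardize = FALSE),
       truth = .truthVector(sc))
}

#' Replication study harness
#'
#' Repeats simulate-then-fit `B` times, fitting each requested family to
#' every replicated dataset, and aggregates the evaluation metrics: average
#' posterior mean, root-mean squared error against the truth, empirical
#' coverage of the central credible sets, and WAIC per family. Child seeds
#' are derived from the master seed so results are independent of scheduling.
#'
#' @param scenario an `efdmScenario`.
#' @param fitFamilies character vector of families to fit.
#' @param B number of replications.
#' @param mcmc MCMC settings applied to each fit.
#' @param seed master seed.
#' @param priors prior settings.
#' @param level credible level for coverage.
#' @param N,readsMean optional scenario size overrides.
#' @return list with `summary` (per family x parameter), `waic` (per
#'   replication x family), `perReplication` (full long table) and `failed`
#'   (count of non-finite fits, excluded and reported).
#' @export
replicationStudy <- function(scenario, fitFamilies = "efdm", B = 10,
                             mcmc = mcmcConfig(), seed = 1,
                             priors = priorConfig(), level = 0.95,
                             N = NULL, readsMean = NULL) {
  stopifnot(B >= 1)
  long <- list(); wrows <- list(); failed <- 0L
  for (b in seq_len(B)) {
    childSeed <- seed + 1009L * b
    sim <- simulateScenario(scenario, seed = childSeed, N = N,
                            readsMean = readsMean)
    for (fam in fitFamilies) {
      m <- mcmc; m$seed <- childSeed + .familyCode(fam)
      fit <- try(fitEFDMReg(sim$data, fam, priors, m), silent = TRUE)
      if (inherits(fit, "try-error")) { failed <- failed + 1L; next }
      ps <- posteriorSummary(fit, level = level, truth = sim$truth)
      ps$rep <- b; ps$family <- fam
      long[[length(long) + 1]] <- ps
      wrows[[length(wrows) + 1]] <-
        data.frame(rep = b, family = fam, waic = waic(fit)$waic)
    }
  }
  long <- do.call(rbind, long)
  keep <- !is.na(long$truth)
  agg <- long[keep, ]
  summary <- do.call(rbind, lapply(
    split(agg, list(agg$family, agg$parameter), drop = TRUE),
    function(d) data.frame(family = d$family[1], parameter = d$parameter[1],
                           truth = d$truth[1],
                           postMean = mean(d$mean),
                           rMSE = sqrt(mean(d$sqErr)),
                           coverage = mean(d$covered))))
  rownames(summary) <- NULL
  list(summary = summary, waic = do.call(rbind, wrows),
       perReplication = long, failed = failed)
}
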