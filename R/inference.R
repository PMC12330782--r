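#' Prior configuration for EFDM-family regression
#'
#' Weakly informative defaults: independent normals with large standard
#' deviation on each regression coefficient, a Gamma prior on the precision
#' with mean `precisionMean` and a small rate (hence large prior variance), a
#' uniform Dirichlet on the mixing weights, and a symmetric Beta on each
#' wtilde. Setting `sparseP = TRUE` replaces the uniform Dirichlet with a
#' symmetric Dirichlet(c/D) that concentrates prior mass on sparse weight
#' vectors.
#'
#' @param coeffSd prior sd of each non-intercept coefficient.
#' @param interceptSd prior sd of each intercept.
#' @param precisionMean prior mean k of alpha+ (Gamma(k g, g)).
#' @param precisionRate small rate g of the Gamma prior.
#' @param wtildeDelta symmetric Beta(delta, delta) parameter for wtilde.
#' @param sparseP logical; use the sparse symmetric Dirichlet on p.
#' @param sparseC constant c of the sparse Dirichlet(c/D).
#' @return list of class `efdmPriors`.
#' @export
priorConfig <- function(coeffSd = 10, interceptSd = 10, precisionMean = 50,
                        precisionRate = 0.01, wtildeDelta = 1,
                        sparseP = FALSE, sparseC = 1) {
  stopifnot(coeffSd > 0, interceptSd > 0, precisionMean > 0,
            precisionRate > 0, wtildeDelta > 0, sparseC > 0)
  structure(list(coeffSd = coeffSd, interceptSd = interceptSd,
                 precisionMean = precisionMean, precisionRate = precisionRate,
                 wtildeDelta = wtildeDelta, sparseP = sparseP,
                 sparseC = sparseC),
            class = "efdmPriors")
}

#' Spike-and-slab configuration for covariate-level variable selection
#'
#' Each covariate's full coefficient vector across the D-1 equations gets a
#' two-component normal mixture prior: a diffuse slab and a narrow spike,
#' mixed by a per-covariate inclusion probability theta_k with a Beta
#' hyperprior. The binary indicator is marginalized out of the sampled
#' density, which keeps the posterior amenable to the continuous sampler.
#'
#' @param slabVar large slab variance (per coefficient).
#' @param spikeVar small spike variance; must be below `slabVar`.
#' @param interceptVar variance of the always-included intercept vector.
#' @param a0,b0 Beta hyperprior on each inclusion probability.
#' @param threshold selection threshold on the posterior mean inclusion
#'   probability (the midpoint of the commonly used 0.1-0.2 band).
#' @return list of class `efdmSpikeSlab`.
#' @export
spikeSlabConfig <- function(slabVar = 10, spikeVar = 0.001,
                            interceptVar = 100, a0 = 1, b0 = 1,
                            threshold = 0.15) {
  if (spikeVar <= 0 || slabVar <= spikeVar)
    stop("need slabVar > spikeVar > 0")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(slabVar = slabVar, spikeVar = spikeVar,
                 interceptVar = interceptVar, a0 = a0, b0 = b0,
                 threshold = threshold),
            class = "efdmSpikeSlab")
}

#' MCMC configuration
#'
#' Settings for the adaptive random-walk Metropolis sampler: the proposal
#' covariance is learned during warmup (empirical covariance of the history,
#' globally rescaled toward the target acceptance rate) and frozen
#' afterwards; only post-warmup, thinned draws are kept.
#'
#' @param chains number of independent chains.
#' @param warmup adaptation iterations per chain (discarded).
#' @param iter post-warmup iterations per chain.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; chain c uses `seed + c` internally.
#' @param targetAccept target acceptance rate of the random-walk proposal.
#' @return list of class `efdmMCMC`.
#' @export
mcmcConfig <- function(chains = 2, warmup = 6000, iter = 6000, thin = 5,
                       seed = 1, targetAccept = 0.234) {
  stopifnot(chains >= 1, warmup >= 200, iter >= thin, thin >= 1,
            targetAccept > 0, targetAccept < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed), targetAccept = targetAccept),
            class = "efdmMCMC")
}

# prior list handed to the C++ log-posterior
.priorList <- function(priors, ss, D) {
  conc <- if (priors$sparseP) rep(priors$sparseC / D, D) else rep(1, D)
  list(coeffSd = priors$coeffSd,
       interceptSd = if (is.null(ss)) priors$interceptSd
                     else sqrt(ss$interceptVar),
       gamShape = priors$precisionMean * priors$precisionRate,
       gamRate = priors$precisionRate,
       dirConc = conc,
       wtBetaA = priors$wtildeDelta, wtBetaB = priors$wtildeDelta,
       slabVar = if (is.null(ss)) 1 else ss$slabVar,
       spikeVar = if (is.null(ss)) 0.5 else ss$spikeVar,
       thetaA = if (is.null(ss)) 1 else ss$a0,
       thetaB = if (is.null(ss)) 1 else ss$b0)
}

# number of unconstrained parameters
.nPar <- function(D, K1, family, spike) {
  P <- (D - 1) * K1
  if (family != "multinomial") P <- P + 1
  if (family %in% c("fdm", "efdm")) P <- P + (D - 1)
  if (family == "fdm") P <- P + 1
  if (family == "efdm") P <- P + D
  if (spike) P <- P + K1 - 1
  P
}

# mirror of the C++ stick-breaking transform
.stickToSimplex <- function(z) {
  D <- length(z) + 1
  p <- numeric(D)
  rest <- 1
  for (k in seq_along(z)) {
    v <- stats::plogis(z[k] - log(D - k))
    p[k] <- rest * v
    rest <- rest - p[k]
  }
  p[D] <- rest
  p
}

.simplexToStick <- function(p) {
  D <- length(p)
  z <- numeric(D - 1)
  rest <- 1
  for (k in seq_len(D - 1)) {
    v <- p[k] / rest
    z[k] <- stats::qlogis(v) + log(D - k)
    rest <- rest - p[k]
  }
  z
}

# pack a named truth/init on the constrained scale into the sampler scale
.packParams <- function(coeffs, aux, family, spike, K) {
  th <- as.numeric(t(coeffs))
  if (family != "multinomial") th <- c(th, log(aux$alphaPlus))
  if (family %in% c("fdm", "efdm")) th <- c(th, .simplexToStick(aux$p))
  if (family == "fdm") th <- c(th, stats::qlogis(aux$wtilde[1]))
  if (family == "efdm") th <- c(th, stats::qlogis(aux$wtilde))
  if (spike) th <- c(th, rep(0, K))
  th
}

# constrained-scale draws with readable column names
.constrainDraws <- function(un, D, K1, family, spike, taxa, baseline,
                            covNames, ss = NULL) {
  K <- K1 - 1
  nB <- (D - 1) * K1
  eqTaxa <- taxa[-baseline]
  bn <- as.vector(t(outer(seq_len(D - 1), 0:K,
                          function(r, k) paste0("beta[", r, ",", k, "]"))))
  out <- un[, seq_len(nB), drop = FALSE]
  colnames(out) <- bn
  idx <- nB
  if (family != "multinomial") {
    out <- cbind(out, alphaPlus = exp(un[, idx + 1]))
    idx <- idx + 1
  }
  if (family %in% c("fdm", "efdm")) {
    z <- un[, idx + seq_len(D - 1), drop = FALSE]
    P <- t(apply(z, 1, .stickToSimplex))
    colnames(P) <- paste0("p[", seq_len(D), "]")
    out <- cbind(out, P)
    idx <- idx + D - 1
  }
  if (family == "fdm") {
    out <- cbind(out, wtilde = stats::plogis(un[, idx + 1]))
    idx <- idx + 1
  }
  if (family == "efdm") {
    W <- stats::plogis(un[, idx + seq_len(D), drop = FALSE])
    colnames(W) <- paste0("wtilde[", seq_len(D), "]")
    out <- cbind(out, W)
    idx <- idx + D
  }
  if (spike) {
    TH <- stats::plogis(un[, idx + seq_len(K), drop = FALSE])
    colnames(TH) <- paste0("theta[", seq_len(K), "]")
    # per-draw responsibility of the slab given the coefficient block
    RS <- matrix(NA_real_, nrow(un), K)
    for (k in seq_len(K)) {
      cols <- (seq_len(D - 1) - 1) * K1 + k + 1
      bk <- un[, cols, drop = FALSE]
      l1 <- log(TH[, k]) +
        rowSums(dnorm(bk, 0, sqrt(ss$slabVar), log = TRUE))
      l0 <- log1p(-TH[, k]) +
        rowSums(dnorm(bk, 0, sqrt(ss$spikeVar), log = TRUE))
      RS[, k] <- 1 / (1 + exp(l0 - l1))
    }
    colnames(RS) <- paste0("incl[", seq_len(K), "]")
    out <- cbind(out, TH, RS)
  }
  attr(out, "equationTaxa") <- eqTaxa
  out
}

# multinomial-logit starting values for the coefficient block
.initCoeffs <- function(Y, X, baseline) {
  D <- ncol(Y)
  ord <- c(baseline, setdiff(seq_len(D), baseline))
  ans <- try({
    fit <- nnet::multinom(Y[, ord] ~ X - 1, trace = FALSE, maxit = 200)
    cf <- coef(fit) # (D-1) x K1 against the first column (= our baseline);
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    cf # rows follow ord[-1], i.e. the non-baseline taxa in ascending order
  }, silent = TRUE)
  if (inherits(ans, "try-error") || any(!is.finite(ans))) {
    matrix(0, D - 1, ncol(X))
  } else {
    pmax(pmin(unname(ans), 8), -8) # keep starts inside a numerically safe box
  }
}

.fitCommon <- function(data, family, priors, mcmc, baseline, ss,
                       likelihoodWeight = 1) {
  Y <- countMatrix(data)
  X <- covariateMatrix(data)
  D <- ncol(Y); K1 <- ncol(X); K <- K1 - 1
  if (is.null(baseline)) baseline <- D
  if (baseline < 1 || baseline > D) stop("invalid baseline index")
  spike <- !is.null(ss)
  if (spike && K < 1) stop("spike-and-slab selection needs at least one covariate")
  famCode <- .familyCode(family)
  pl <- .priorList(priors, ss, D)
  P <- .nPar(D, K1, family, spike)

  coef0 <- if (likelihoodWeight > 0) .initCoeffs(Y, X, baseline)
           else matrix(0, D - 1, K1)
  base0 <- .packParams(coef0,
                       list(alphaPlus = priors$precisionMean,
                            p = rep(1 / D, D), wtilde = rep(0.5, D)),
                       family, spike, K)

  chains <- vector("list", mcmc$chains)
  accept <- numeric(mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch)
    for (attempt in 1:5) {
      init <- base0 + rnorm(P, 0, 0.1 / attempt)
      lp <- cpp_log_posterior(Y, X, init, baseline - 1L, famCode, spike,
                              likelihoodWeight, pl)
      if (is.finite(lp)) break
      if (attempt == 5) stop("could not find a finite starting point")
    }
    res <- cpp_run_am(Y, X, init, baseline - 1L, famCode, spike,
                      likelihoodWeight, pl, mcmc$warmup, mcmc$iter,
                      mcmc$thin, mcmc$targetAccept)
    chains[[ch]] <- res
    accept[ch] <- res$acceptRate
  }
  un <- do.call(rbind, lapply(chains, `[[`, "draws"))
  ll <- do.call(rbind, lapply(chains, `[[`, "loglik"))
  taxa <- taxonNames(data)
  covNames <- colnames(X)
  draws <- .constrainDraws(un, D, K1, family, spike, taxa, baseline,
                           covNames, ss)
  Sper <- nrow(chains[[1]]$draws)
  diag <- .chainDiagnostics(lapply(chains, `[[`, "draws"))
  diag$acceptRate <- accept
  diag$seed <- mcmc$seed
  diag$chains <- mcmc$chains
  diag$drawsPerChain <- Sper
  diag$divergent <- 0L # random-walk proposals have no divergence notion
  colnames(ll) <- rownames(Y)
  new("EFDMFit", draws = draws, unconstrained = un, logLikMatrix = ll,
      family = family, baseline = as.integer(baseline), taxa = taxa,
      covariates = covNames, diagnostics = diag,
      spikeSlab = spike,
      config = list(priors = priors, mcmc = mcmc, spikeSlabConfig = ss,
                    likelihoodWeight = likelihoodWeight))
}

#' Fit an EFDM-family mean regression by MCMC
#'
#' Bayesian estimation of the multinomial-logit mean regression under the
#' multinomial, Dirichlet-multinomial, flexible DM or extended flexible DM
#' response family, with the weakly informative priors of [priorConfig()].
#' Only the mean is regressed on covariates; the precision, mixing weights
#' and wtilde are global. Sampling uses adaptive random-walk Metropolis on an
#' unconstrained reparameterization (log precision, stick-breaking weights,
#' logit wtilde) with the matching Jacobians.
#'
#' @param data an [EFDMExperiment-class].
#' @param family response family.
#' @param priors an `efdmPriors` list from [priorConfig()].
#' @param mcmc an `efdmMCMC` list from [mcmcConfig()].
#' @param baseline baseline taxon index (default: last taxon).
#' @param likelihoodWeight internal dial in `[0, 1]`; 0 samples the prior
#'   (used by prior-predictive checks).
#' @return an [EFDMFit-class] object.
#' @examples
#' sc <- caseIVScenario()
#' sim <- simulateScenario(sc, seed = 1, N = 60, readsMean = 40)
#' fit <- fitEFDMReg(sim$data, family = "dm",
#'                   mcmc = mcmcConfig(chains = 1, warmup = 400, iter = 300,
#'                                     thin = 3, seed = 1))
#' @export
fitEFDMReg <- function(data, family = c("efdm", "fdm", "dm", "multinomial"),
                       priors = priorConfig(), mcmc = mcmcConfig(),
                       baseline = NULL, likelihoodWeight = 1) {
  family <- match.arg(family)
  .fitCommon(data, family, priors, mcmc, baseline, ss = NULL,
             likelihoodWeight = likelihoodWeight)
}

#' Fit with the spike-and-slab variable-selection prior
#'
#' Same sampler and likelihood as [fitEFDMReg()], but each covariate's
#' coefficient vector across equations receives the marginalized
#' spike-and-slab mixture prior of [spikeSlabConfig()], and per-covariate
#' inclusion probabilities theta_k are sampled under their Beta hyperprior.
#' The posterior draws gain `theta[k]` columns (sampled inclusion
#' probabilities) and `incl[k]` columns (per-draw slab responsibilities).
#'
#' @inheritParams fitEFDMReg
#' @param ss an `efdmSpikeSlab` list from [spikeSlabConfig()].
#' @return an [EFDMFit-class] object with `spikeSlab = TRUE`.
#' @export
fitSpikeSlab <- function(data, family = c("efdm", "fdm", "dm", "multinomial"),
                         ss = spikeSlabConfig(), priors = priorConfig(),
                         mcmc = mcmcConfig(), baseline = NULL) {
  family <- match.arg(family)
  .fitCommon(data, family, priors, mcmc, baseline, ss = ss)
}

#' @describeIn posteriorDraws accessor.
#' @export
setMethod("posteriorDraws", "EFDMFit", function(object) object@draws)

#' @describeIn logLikMatrix accessor.
#' @export
setMethod("logLikMatrix", "EFDMFit", function(object) object@logLikMatrix)

#' @describeIn diagnostics accessor.
#' @export
setMethod("diagnostics", "EFDMFit", function(object) object@diagnostics)

setMethod("show", "EFDMFit", function(object) {
  d <- object@diagnostics
  cat("EFDMFit: family =", object@family,
      if (object@spikeSlab) "(spike-and-slab)" else "", "\n")
  cat("  draws:", nrow(object@draws), "(", d$chains, "chains x",
      d$drawsPerChain, ")\n")
  cat("  acceptance:", paste(round(d$acceptRate, 3), collapse = ", "), "\n")
  cat("  max split R-hat:", round(max(d$rhat, na.rm = TRUE), 3),
      " min ESS:", round(min(d$ess, na.rm = TRUE)), "\n")
})

# split R-hat and a Geyer-style initial-positive-sequence ESS, computed on
# the unconstrained draws
.chainDiagnostics <- function(chainList) {
  S <- nrow(chainList[[1]])
  P <- ncol(chainList[[1]])
  half <- floor(S / 2)
  splits <- list()
  for (ch in chainList) {
    splits[[length(splits) + 1]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1]] <- ch[(half + 1):(2 * half), , drop = FALSE]
  }
  m <- length(splits)
  rhat <- ess <- numeric(P)
  for (j in seq_len(P)) {
    xs <- vapply(splits, function(s) s[, j], numeric(half))
    mns <- colMeans(xs)
    vars <- apply(xs, 2, var)
    W <- mean(vars)
    B <- half * var(mns)
    rhat[j] <- if (W > 0) sqrt(((half - 1) / half * W + B / half) / W) else NA
    # ESS from pooled autocorrelations
    rho <- 0
    x <- as.vector(xs)
    v <- var(x)
    if (v > 0) {
      ac <- stats::acf(x, lag.max = min(200, half - 1), plot = FALSE,
                       demean = TRUE)$acf[-1]
      csum <- 0
      for (l in seq(1, length(ac) - 1, by = 2)) {
        pair <- ac[l] + ac[l + 1]
        if (is.na(pair) || pair < 0) break
        csum <- csum + pair
      }
      rho <- csum
    }
    ess[j] <- length(x) / (1 + 2 * rho)
  }
  list(rhat = rhat, ess = ess)
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, sd and central (equal-tailed) credible
#' interval; when a named truth vector is supplied, squared errors and
#' coverage flags are added.
#'
#' @param object an [EFDMFit-class] or a draws matrix with named columns.
#' @param level credible level in (0, 1).
#' @param truth optional named numeric vector of true values.
#' @return a data.frame with one row per parameter.
#' @export
posteriorSummary <- function(object, level = 0.95, truth = NULL) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  draws <- if (is(object, "EFDMFit")) posteriorDraws(object) else as.matrix(object)
  a <- (1 - level) / 2
  qs <- t(apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE))
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    sd = apply(draws, 2, sd),
                    lower = qs[, 1], upper = qs[, 2],
                    row.names = NULL)
  if (!is.null(truth)) {
    idx <- match(out$parameter, names(truth))
    out$truth <- truth[idx]
    out$sqErr <- (out$mean - out$truth)^2
    out$covered <- !is.na(out$truth) &
      out$lower <= out$truth & out$truth <= out$upper
  }
  out
}

#' Widely applicable information criterion
#'
#' WAIC computed from an S x N matrix of per-sample posterior
#' log-likelihoods: `lppd` is the sum over samples of the log of the
#' posterior-mean likelihood (via log-sum-exp), the effective number of
#' parameters `pWaic` is the sum of per-sample posterior variances of the
#' log-likelihood, and `waic = -2 (lppd - pWaic)`. Lower is better.
#'
#' @param x an S x N log-likelihood matrix or an [EFDMFit-class].
#' @return list with components `waic`, `lppd`, `pWaic`.
#' @examples
#' waic(matrix(c(log(.5), log(.25), log(.5), log(.75)), 2, 2))
#' @export
waic <- function(x) {
  ll <- if (is(x, "EFDMFit")) logLikMatrix(x) else as.matrix(x)
  if (nrow(ll) < 2) stop("need at least two posterior draws")
  if (any(!is.finite(ll))) stop("log-likelihood matrix has non-finite entries")
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  pw <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - pw), lppd = lppd, pWaic = pw)
}
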