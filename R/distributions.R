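#' Dirichlet-multinomial log probability mass function
#'
#' Density of the Dirichlet-multinomial distribution in its (mean, precision)
#' parameterization: the multinomial probability vector is integrated over a
#' Dirichlet with mean `mu` and precision `alphaPlus`. Evaluated through
#' log-gamma functions, so totals up to 1e5 and beyond are handled without
#' overflow.
#'
#' @param x count vector of length D, or a matrix with D columns (one count
#'   vector per row).
#' @param mu mean vector on the simplex.
#' @param alphaPlus positive precision; as it grows the distribution
#'   approaches the multinomial with probabilities `mu`.
#' @param log logical; return log-density?
#' @return numeric vector of (log-)densities.
#' @examples
#' ddm(c(2, 1, 1), mu = c(0.2, 0.3, 0.5), alphaPlus = 2)
#' @export
ddm <- function(x, mu, alphaPlus, log = FALSE) {
  x <- .asCountMatrix(x, length(mu))
  if (any(mu <= 0) || abs(sum(mu) - 1) > 1e-8)
    stop("'mu' must be strictly positive and sum to 1")
  if (length(alphaPlus) != 1 || !is.finite(alphaPlus) || alphaPlus <= 0)
    stop("'alphaPlus' must be a positive scalar")
  n <- rowSums(x)
  if (any(n < 1)) stop("each count vector must have a positive total")
  a <- matrix(alphaPlus * mu, nrow(x), ncol(x), byrow = TRUE)
  ll <- lgamma(n + 1) - rowSums(lgamma(x + 1)) +
    lgamma(alphaPlus) - lgamma(alphaPlus + n) +
    rowSums(lgamma(a + x) - lgamma(a))
  if (log) ll else exp(ll)
}

#' Extended flexible Dirichlet-multinomial log probability mass function
#'
#' Evaluates the EFDM density as a finite mixture of Dirichlet-multinomial
#' components via log-sum-exp: component r has concentration
#' \eqn{\alpha + \tau_r e_r} and weight \eqn{p_r}; components with
#' \eqn{p_r = 0} are skipped.
#'
#' @param x count vector of length D or matrix with D columns.
#' @param params an [EFDMParams-class] or [EFDMMeanParams-class] object.
#' @param log logical; return log-density?
#' @return numeric vector of (log-)densities.
#' @examples
#' sp <- efdmParams(c(1, 2, 3), c(2, 1, 4), c(0.2, 0.3, 0.5))
#' defdm(c(2, 2, 1), sp, log = TRUE)
#' @export
defdm <- function(x, params, log = FALSE) {
  params <- asStandardParams(params)
  alpha <- params@alpha; tau <- params@tau; p <- params@p
  D <- length(alpha)
  x <- .asCountMatrix(x, D)
  n <- rowSums(x)
  if (any(n < 1)) stop("each count vector must have a positive total")
  ap <- sum(alpha)
  comp <- matrix(-Inf, nrow(x), D)
  base <- lgamma(n + 1) - rowSums(lgamma(x + 1))
  for (r in which(p > 0)) {
    a <- matrix(alpha, nrow(x), D, byrow = TRUE)
    a[, r] <- a[, r] + tau[r]
    C <- ap + tau[r]
    comp[, r] <- log(p[r]) + lgamma(C) - lgamma(C + n) +
      rowSums(lgamma(a + x) - lgamma(a))
  }
  m <- apply(comp, 1, max)
  ll <- base + m + log(rowSums(exp(comp - m)))
  if (log) ll else exp(ll)
}

#' Sample EFDM count vectors
#'
#' Draws from the generative hierarchy: a component label from the mixing
#' weights, a probability vector from the component's Dirichlet, then
#' multinomial counts.
#'
#' @param totals vector of positive integer totals, one per draw.
#' @param params an [EFDMParams-class] or [EFDMMeanParams-class] object.
#' @param seed optional integer; when supplied, the RNG seed is set locally.
#' @return an `length(totals)` x D integer matrix whose rows sum to `totals`.
#' @examples
#' sp <- efdmParams(c(1, 2, 3), c(2, 1, 4), c(0.2, 0.3, 0.5))
#' refdm(rep(20, 5), sp, seed = 1)
#' @export
refdm <- function(totals, params, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  params <- asStandardParams(params)
  alpha <- params@alpha; tau <- params@tau; p <- params@p
  D <- length(alpha)
  stopifnot(all(totals >= 1))
  N <- length(totals)
  comp <- sample.int(D, N, replace = TRUE, prob = p)
  conc <- matrix(alpha, N, D, byrow = TRUE)
  conc[cbind(seq_len(N), comp)] <- conc[cbind(seq_len(N), comp)] + tau[comp]
  g <- matrix(rgamma(N * D, shape = conc), N, D)
  pi <- g / rowSums(g)
  out <- matrix(0L, N, D)
  for (i in seq_len(N)) out[i, ] <- rmultinom(1, totals[i], pi[i, ])
  out
}

#' Normalized variance of a bounded random variable
#'
#' For a variable with support in `[0, upper]`, the variance is bounded by
#' `mean * (upper - mean)`; the normalized variance is the ratio of the two,
#' and for counts with fixed total n it ranges over `[1/n, 1]` (1/n at the
#' multinomial benchmark).
#'
#' @param var nonnegative variance.
#' @param mean mean, strictly inside (0, upper).
#' @param upper upper bound of the support.
#' @return `var / (mean * (upper - mean))`.
#' @export
normalizedVariance <- function(var, mean, upper) {
  if (any(mean <= 0) || any(mean >= upper))
    stop("'mean' must lie strictly inside (0, upper)")
  if (any(var < 0)) stop("'var' must be nonnegative")
  var / (mean * (upper - mean))
}

#' Mean and covariance of the EFD-distributed probability vector
#'
#' Moments of the latent composition \eqn{\Pi} under the extended flexible
#' Dirichlet: the mixture of Dirichlet components with means
#' \eqn{\lambda_r} and precisions \eqn{\alpha^+ + \tau_r}. These drive the
#' large-n dependence structure of the counts (the count correlations
#' converge to the \eqn{\Pi} correlations).
#'
#' @param params an [EFDMParams-class] or [EFDMMeanParams-class] object.
#' @return list with `mean` (length D) and `cov` (D x D).
#' @export
efdMoments <- function(params) {
  params <- asStandardParams(params)
  p <- params@p
  ap <- sum(params@alpha)
  phi <- ap + params@tau
  lam <- componentMeans(params)
  mu <- as.numeric(p %*% lam)
  D <- length(mu)
  V <- matrix(0, D, D)
  for (r in seq_len(D)) {
    lr <- lam[r, ]
    Vr <- (diag(lr) - tcrossprod(lr)) / (phi[r] + 1)
    V <- V + p[r] * (Vr + tcrossprod(lr))
  }
  V <- V - tcrossprod(mu)
  list(mean = mu, cov = (V + t(V)) / 2)
}

.momentsFromPi <- function(mu, VPi, n, taxa = NULL) {
  D <- length(mu)
  Mmu <- diag(mu) - tcrossprod(mu)
  cov <- n * Mmu + n * (n - 1) * VPi
  denom <- mu * (1 - mu)
  intra <- diag(VPi) / denom
  inter <- VPi / tcrossprod(sqrt(denom))
  diag(inter) <- NA_real_
  nvar <- diag(cov) / (n * mu * (n - n * mu))
  if (!is.null(taxa)) {
    names(intra) <- names(nvar) <- taxa
    dimnames(cov) <- dimnames(inter) <- list(taxa, taxa)
  }
  new("EFDMMoments", mean = n * mu, cov = cov, nvar = nvar,
      intraclass = intra, interclass = inter, size = n)
}

#' Moments and class correlations of the EFDM distribution
#'
#' Computes the mean, covariance, normalized variances and the inter-/
#' intraclass correlations of single-read indicators for counts with total
#' `size`, using the law of total variance over the latent EFD composition.
#' The intraclass correlation equals the normalized variance of \eqn{\Pi_r}
#' and the interclass correlation is the indicator-level correlation between
#' different taxa; both are free of `size`.
#'
#' @param params an [EFDMParams-class] or [EFDMMeanParams-class] object.
#' @param size positive integer count total n.
#' @param taxa optional character labels.
#' @return an [EFDMMoments-class] object.
#' @examples
#' sp <- efdmParams(c(1, 2, 3), c(2, 1, 4), c(0.2, 0.3, 0.5))
#' efdmMoments(sp, size = 50)
#' @export
efdmMoments <- function(params, size, taxa = NULL) {
  if (length(size) != 1 || size < 1) stop("'size' must be a positive integer")
  em <- efdMoments(params)
  .momentsFromPi(em$mean, em$cov, size, taxa)
}

#' Moments of the flexible Dirichlet-multinomial (equal-tau) sub-model
#'
#' Closed-form moments of the FDM distribution, the EFDM sub-model in which
#' all vertex displacements share a common value tau so that every mixture
#' component has the same precision \eqn{\phi = \alpha^+ + \tau}. The
#' covariance is the Dirichlet-multinomial one inflated by a term
#' proportional to the centering matrix of the mixing weights:
#' \deqn{V(Y) = n M(\mu)(1 + (n-1)/(\phi+1)) +
#'   n(n-1) \tau^2 M(p) / (\phi(\phi+1))}
#' with matching closed forms for the class correlations. Results agree with
#' [efdmMoments()] on the same parameters; the two routes are algebraically
#' independent implementations.
#'
#' @param params an [EFDMParams-class] with all tau equal (or a mean-level
#'   object mapping to one).
#' @param size positive integer count total.
#' @param taxa optional character labels.
#' @return an [EFDMMoments-class] object.
#' @export
fdmMoments <- function(params, size, taxa = NULL) {
  params <- asStandardParams(params)
  tau <- params@tau; p <- params@p
  if (diff(range(tau)) > 1e-12)
    stop("FDM moments require a common tau across components")
  tau <- tau[1]
  if (length(size) != 1 || size < 1) stop("'size' must be a positive integer")
  ap <- sum(params@alpha)
  phi <- ap + tau
  w <- tau / phi
  mu <- (1 - w) * params@alpha / ap + w * p
  D <- length(mu)
  n <- size
  Mmu <- diag(mu) - tcrossprod(mu)
  Mp <- diag(p) - tcrossprod(p)
  cov <- n * Mmu * (1 + (n - 1) / (phi + 1)) +
    n * (n - 1) * tau^2 * Mp / (phi * (phi + 1))
  odds <- mu / (1 - mu)
  intra <- (1 + (tau^2 / phi) * p * (1 - p) / (mu * (1 - mu))) / (phi + 1)
  inter <- -(1 / (phi + 1)) * tcrossprod(sqrt(odds)) *
    (1 + (tau^2 / phi) * tcrossprod(p) / tcrossprod(mu))
  diag(inter) <- NA_real_
  nvar <- diag(cov) / (n * mu * (n - n * mu))
  if (!is.null(taxa)) {
    names(intra) <- names(nvar) <- taxa
    dimnames(cov) <- dimnames(inter) <- list(taxa, taxa)
  }
  new("EFDMMoments", mean = n * mu, cov = cov, nvar = nvar,
      intraclass = intra, interclass = inter, size = n)
}

#' Enumerate the discrete simplex
#'
#' All vectors of D nonnegative integers summing to n: the support of the
#' count distributions in this package. Useful for exact (brute-force)
#' normalization and moment checks at small D and n.
#'
#' @param D number of parts.
#' @param n total.
#' @return a `choose(n + D - 1, D - 1)` x D integer matrix.
#' @export
simplexGrid <- function(D, n) {
  if (D == 1) return(matrix(n, 1, 1))
  out <- lapply(0:n, function(k) cbind(k, simplexGrid(D - 1, n - k)))
  m <- do.call(rbind, lapply(out, unname))
  dimnames(m) <- NULL
  m
}

setMethod("show", "EFDMMoments", function(object) {
  cat("EFDMMoments (D = ", length(object@mean), ", n = ", object@size, ")\n",
      sep = "")
  m <- rbind(mean = object@mean, nvar = object@nvar,
             intraclass = object@intraclass)
  print(round(m, 4))
  cat("interclass range: [",
      format(min(object@interclass, na.rm = TRUE), digits = 3), ", ",
      format(max(object@interclass, na.rm = TRUE), digits = 3), "]\n", sep = "")
})

.asCountMatrix <- function(x, D) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != D) stop("count vectors must have length ", D)
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be nonnegative integers")
  storage.mode(x) <- "double"
  x
}
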