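#' @import methods
#' @importFrom stats rnorm rgamma rpois rmultinom runif setNames var quantile
#'   sd logLik rbeta cor dnorm
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib EFDMreg, .registration = TRUE
NULL

#' Natural (alpha, tau, p) parameterization of the EFDM family
#'
#' The extended flexible Dirichlet-multinomial (EFDM) distribution is a
#' structured finite mixture of Dirichlet-multinomial components: component
#' \eqn{r} has barycenter \eqn{\lambda_r = (\alpha + \tau_r e_r)/(\alpha^+ +
#' \tau_r)} and precision \eqn{\alpha^+ + \tau_r}, and receives mixing weight
#' \eqn{p_r}. This class stores the natural parameters.
#'
#' @slot alpha positive D-vector; \eqn{\alpha^+ = \sum_r \alpha_r} is the
#'   common precision of the shared barycenter.
#' @slot tau positive D-vector of vertex displacements; by convention
#'   \eqn{\tau_r} is pinned to 1 for components with \eqn{p_r = 0}.
#' @slot p mixing weights on the simplex, each strictly below 1 (zeros
#'   allowed).
#'
#' @seealso [efdmParams()], [efdmMeanParams()], [defdm()], [efdmMoments()]
#' @export
setClass("EFDMParams",
  representation(alpha = "numeric", tau = "numeric", p = "numeric"),
  validity = function(object) {
    D <- length(object@alpha)
    if (D < 2) return("need at least two categories")
    if (length(object@tau) != D || length(object@p) != D)
      return("alpha, tau and p must have equal length")
    if (any(!is.finite(object@alpha)) || any(object@alpha <= 0))
      return("all alpha must be finite and positive")
    if (any(!is.finite(object@tau)) || any(object@tau <= 0))
      return("all tau must be finite and positive")
    if (any(object@p < 0) || any(object@p >= 1))
      return("mixing weights must lie in [0, 1)")
    if (abs(sum(object@p) - 1) > 1e-8)
      return("mixing weights must sum to 1")
    if (any(object@p == 0 & object@tau != 1))
      return("tau must equal 1 for components with p = 0")
    TRUE
  }
)

#' Mean-level (mu, alpha+, p, wtilde) parameterization of the EFDM family
#'
#' Variation-independent parameterization used by the regression model: the
#' marginal mean \eqn{\mu = E[Y/n]} is free on the simplex, the precision
#' \eqn{\alpha^+} is free on the positive reals, the mixing weights \eqn{p}
#' are free on the simplex, and the normalized vertex-pull parameters
#' \eqn{\tilde w_r \in (0,1)} replace \eqn{w_r = \tau_r/(\alpha^+ + \tau_r)}
#' via \eqn{\tilde w_r = w_r / \min(1, \mu_r / p_r)}.
#'
#' @slot mu mean vector on the simplex (strictly positive entries).
#' @slot alphaPlus positive precision scalar.
#' @slot p mixing weights as in [EFDMParams-class].
#' @slot wtilde D-vector in (0,1); by convention 1/2 where \eqn{p_r = 0}.
#'
#' @seealso [efdmMeanParams()], [asStandardParams()]
#' @export
setClass("EFDMMeanParams",
  representation(mu = "numeric", alphaPlus = "numeric", p = "numeric",
                 wtilde = "numeric"),
  validity = function(object) {
    D <- length(object@mu)
    if (D < 2) return("need at least two categories")
    if (length(object@p) != D || length(object@wtilde) != D)
      return("mu, p and wtilde must have equal length")
    if (any(object@mu <= 0) || abs(sum(object@mu) - 1) > 1e-8)
      return("mu must be strictly positive and sum to 1")
    if (length(object@alphaPlus) != 1 || !is.finite(object@alphaPlus) ||
        object@alphaPlus <= 0)
      return("alphaPlus must be a positive scalar")
    if (any(object@p < 0) || any(object@p >= 1) ||
        abs(sum(object@p) - 1) > 1e-8)
      return("p must lie in [0,1) and sum to 1")
    if (any(object@wtilde <= 0) || any(object@wtilde >= 1))
      return("wtilde must lie strictly inside (0, 1)")
    TRUE
  }
)

#' Moment summary of a count distribution on the discrete simplex
#'
#' @slot mean expected counts (length D).
#' @slot cov D x D covariance matrix of the counts; rows sum to zero because
#'   the counts sum to the fixed total.
#' @slot nvar normalized variances \eqn{Var(Y_r)/(E Y_r (n - E Y_r))}, each in
#'   \eqn{[1/n, 1]}.
#' @slot intraclass per-taxon intraclass correlations of single-read
#'   indicators (equal to the normalized variance of \eqn{\Pi_r}).
#' @slot interclass D x D interclass correlation matrix of single-read
#'   indicators across taxa; the diagonal is NA by construction (the
#'   within-taxon quantity is the intraclass slot).
#' @slot size the count total n the count-level moments refer to.
#' @export
setClass("EFDMMoments",
  representation(mean = "numeric", cov = "matrix", nvar = "numeric",
                 intraclass = "numeric", interclass = "matrix",
                 size = "numeric"))

#' Container for a taxa-by-sample count table with sample covariates
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' `counts` assay (taxa in rows, samples in columns, matching the usual
#' feature-by-sample orientation) and the regression covariates in `colData`.
#' Use [efdmExperiment()] to build one from a samples-by-taxa matrix.
#'
#' @export
setClass("EFDMExperiment", contains = "SummarizedExperiment")

#' Fitted posterior for an EFDM-family regression model
#'
#' @slot draws S x P matrix of posterior draws on the constrained scale
#'   (named columns).
#' @slot unconstrained S x P matrix of draws on the sampler's scale.
#' @slot logLikMatrix S x N matrix of per-sample log-likelihoods.
#' @slot family one of "multinomial", "dm", "fdm", "efdm".
#' @slot baseline taxon index whose coefficient vector is fixed at zero.
#' @slot taxa,covariates character labels.
#' @slot diagnostics list with acceptance rates, split R-hat, effective sample
#'   sizes, chain/iteration counts and the seed.
#' @slot spikeSlab logical; TRUE when fitted with the spike-and-slab prior.
#' @slot config list with the prior and MCMC configurations used.
#' @export
setClass("EFDMFit",
  representation(draws = "matrix", unconstrained = "matrix",
                 logLikMatrix = "matrix", family = "character",
                 baseline = "integer", taxa = "character",
                 covariates = "character", diagnostics = "list",
                 spikeSlab = "logical", config = "list"))
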