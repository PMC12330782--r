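#' Convert to the natural (alpha, tau, p) parameterization
#' @param x an [EFDMMeanParams-class] (or [EFDMParams-class], returned as is).
#' @return an [EFDMParams-class] object.
#' @export
setGeneric("asStandardParams", function(x) standardGeneric("asStandardParams"))

#' Convert to the mean-level (mu, alpha+, p, wtilde) parameterization
#' @param x an [EFDMParams-class] (or [EFDMMeanParams-class], returned as is).
#' @return an [EFDMMeanParams-class] object.
#' @export
setGeneric("asMeanParams", function(x) standardGeneric("asMeanParams"))

#' Posterior draws on the constrained scale
#' @param object an [EFDMFit-class].
#' @return an S x P numeric matrix with named columns.
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' Per-sample log-likelihood matrix of a fit
#' @param object an [EFDMFit-class].
#' @return an S x N numeric matrix.
#' @export
setGeneric("logLikMatrix", function(object) standardGeneric("logLikMatrix"))

#' Sampler diagnostics of a fit
#' @param object an [EFDMFit-class].
#' @return a list (acceptance rates, split R-hat, ESS, seed, ...).
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
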