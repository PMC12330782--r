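#' Construct natural EFDM parameters
#'
#' @param alpha positive D-vector.
#' @param tau positive D-vector; entries matching `p == 0` components are
#'   pinned to 1 (the conventional value for empty components).
#' @param p mixing weights on the simplex, each strictly below 1.
#' @return an [EFDMParams-class] object.
#' @examples
#' sp <- efdmParams(alpha = c(1, 2, 3), tau = c(2, 1, 4),
#'                  p = c(0.2, 0.3, 0.5))
#' @export
efdmParams <- function(alpha, tau, p) {
  stopifnot(is.numeric(alpha), is.numeric(tau), is.numeric(p))
  tau[p == 0] <- 1
  new("EFDMParams", alpha = as.numeric(alpha), tau = as.numeric(tau),
      p = as.numeric(p))
}

#' Construct mean-level EFDM parameters
#'
#' @param mu mean vector on the simplex.
#' @param alphaPlus positive precision scalar.
#' @param p mixing weights (zeros allowed).
#' @param wtilde D-vector in (0,1); entries matching `p == 0` are set to the
#'   conventional value 1/2.
#' @return an [EFDMMeanParams-class] object.
#' @examples
#' mp <- efdmMeanParams(mu = c(0.2, 0.3, 0.5), alphaPlus = 50,
#'                      p = c(0.25, 0.25, 0.5), wtilde = c(0.6, 0.8, 0.7))
#' @export
efdmMeanParams <- function(mu, alphaPlus, p, wtilde) {
  wtilde[p == 0] <- 0.5
  new("EFDMMeanParams", mu = as.numeric(mu), alphaPlus = as.numeric(alphaPlus),
      p = as.numeric(p), wtilde = as.numeric(wtilde))
}

# keep wtilde strictly inside the unit interval when mapping between
# parameterizations, so the bijection stays numerically stable
.WT_EPS <- 1e-6

#' @describeIn asStandardParams map (mu, alpha+, p, wtilde) to (alpha, tau, p);
#'   exact inverse of [asMeanParams()] on the valid region.
#' @export
setMethod("asStandardParams", "EFDMMeanParams", function(x) {
  mu <- x@mu; p <- x@p; ap <- x@alphaPlus
  w <- x@wtilde * pmin(1, ifelse(p > 0, mu / p, 1))
  w[p == 0] <- 0 # empty components do not displace the barycenter
  S <- sum(p * w)
  abar <- (mu - p * w) / (1 - S)
  if (any(abar <= 0))
    stop("internal inconsistency: implied barycenter is not positive")
  tau <- ifelse(p > 0, ap * w / (1 - w), 1)
  efdmParams(alpha = ap * abar, tau = tau, p = p)
})

#' @describeIn asStandardParams identity.
#' @export
setMethod("asStandardParams", "EFDMParams", function(x) x)

#' @describeIn asMeanParams map (alpha, tau, p) to (mu, alpha+, p, wtilde).
#' @export
setMethod("asMeanParams", "EFDMParams", function(x) {
  ap <- sum(x@alpha)
  lam <- componentMeans(x)
  mu <- as.numeric(x@p %*% lam)
  w <- x@tau / (ap + x@tau)
  wt <- ifelse(x@p > 0, w / pmin(1, mu / x@p), 0.5)
  wt <- pmin(pmax(wt, .WT_EPS), 1 - .WT_EPS)
  efdmMeanParams(mu = mu, alphaPlus = ap, p = x@p, wtilde = wt)
})

#' @describeIn asMeanParams identity.
#' @export
setMethod("asMeanParams", "EFDMMeanParams", function(x) x)

#' Component barycenters of the EFDM mixture
#'
#' Returns the D x D matrix whose r-th row is \eqn{\lambda_r = (\alpha +
#' \tau_r e_r)/(\alpha^+ + \tau_r)}, the mean vector of the r-th
#' Dirichlet-multinomial component.
#'
#' @param params an [EFDMParams-class] object.
#' @return D x D matrix of component means (rows on the simplex).
#' @export
componentMeans <- function(params) {
  params <- asStandardParams(params)
  ap <- sum(params@alpha)
  D <- length(params@alpha)
  lam <- matrix(params@alpha, D, D, byrow = TRUE) + diag(params@tau)
  lam / (ap + params@tau)
}

setMethod("show", "EFDMParams", function(object) {
  D <- length(object@alpha)
  cat("EFDMParams (D = ", D, ", alpha+ = ",
      format(sum(object@alpha), digits = 4), ")\n", sep = "")
  m <- rbind(alpha = object@alpha, tau = object@tau, p = object@p)
  colnames(m) <- paste0("c", seq_len(D))
  print(round(m, 4))
})

setMethod("show", "EFDMMeanParams", function(object) {
  D <- length(object@mu)
  cat("EFDMMeanParams (D = ", D, ", alpha+ = ",
      format(object@alphaPlus, digits = 4), ")\n", sep = "")
  m <- rbind(mu = object@mu, p = object@p, wtilde = object@wtilde)
  colnames(m) <- paste0("c", seq_len(D))
  print(round(m, 4))
})
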