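#' Multinomial-logit mean from regression coefficients
#'
#' Inverse link of the mean regression: row i of the result is
#' \eqn{\mu_i = softmax(x_i^T B^T)} where the baseline taxon's coefficient
#' vector is fixed at zero, so non-baseline coefficients are log-odds against
#' the baseline.
#'
#' @param coeffs (D-1) x (K+1) matrix of coefficients for the non-baseline
#'   taxa (in taxon order, baseline row omitted), or a full D x (K+1) matrix
#'   whose baseline row is zero.
#' @param x covariate matrix N x (K+1) (leading intercept column) or a single
#'   covariate vector.
#' @param baseline index of the baseline taxon (default: last).
#' @return N x D matrix of mean vectors (rows on the simplex).
#' @examples
#' B <- rbind(c(-4, 1), c(1.5, -2)) # D = 3, one covariate, baseline 3rd
#' logitLinkMean(B, c(1, 0))
#' @export
logitLinkMean <- function(coeffs, x, baseline = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  coeffs <- as.matrix(coeffs)
  if (is.null(baseline)) baseline <- nrow(coeffs) + 1
  B <- .fullCoefMatrix(coeffs, baseline)
  if (ncol(x) != ncol(B)) stop("covariate dimension does not match coefficients")
  eta <- x %*% t(B)
  eta <- eta - apply(eta, 1, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

# expand a reduced (D-1) x (K+1) matrix to the full D x (K+1) version with a
# zero row at the baseline index
.fullCoefMatrix <- function(coeffs, baseline) {
  D <- nrow(coeffs) + 1
  if (baseline < 1 || baseline > D) stop("invalid baseline index")
  full <- matrix(0, D, ncol(coeffs))
  full[-baseline, ] <- coeffs
  full
}

.familyCode <- function(family) {
  match(match.arg(family, c("multinomial", "dm", "fdm", "efdm")),
        c("multinomial", "dm", "fdm", "efdm")) - 1L
}

#' Per-sample log-likelihood of an EFDM-family regression model
#'
#' Element i is the log density of the i-th count vector under the chosen
#' family with mean \eqn{\mu_i} given by [logitLinkMean()]. The EFDM family
#' maps \eqn{(\mu_i, \alpha^+, p, \tilde w)} to natural parameters per sample
#' and evaluates the mixture density; the FDM family uses a common
#' \eqn{\tilde w}.
#'
#' @param data an [EFDMExperiment-class].
#' @param coeffs (D-1) x (K+1) coefficient matrix (baseline row omitted).
#' @param family one of "multinomial", "dm", "fdm", "efdm".
#' @param aux named list of family-specific parameters: `alphaPlus` (dm, fdm,
#'   efdm), `p` (fdm, efdm), `wtilde` (scalar for fdm, D-vector for efdm).
#' @param baseline baseline taxon index (default last).
#' @return numeric N-vector of per-sample log-likelihoods.
#' @export
regLogLik <- function(data, coeffs, family = c("efdm", "fdm", "dm",
                                               "multinomial"),
                      aux = list(), baseline = NULL) {
  family <- match.arg(family)
  Y <- countMatrix(data)
  X <- covariateMatrix(data)
  D <- ncol(Y)
  if (is.null(baseline)) baseline <- D
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != D - 1 || ncol(coeffs) != ncol(X))
    stop("coefficient matrix must be (D-1) x (K+1)")
  mu <- logitLinkMean(coeffs, X, baseline)
  n <- rowSums(Y)
  base <- lgamma(n + 1) - rowSums(lgamma(Y + 1))
  if (family == "multinomial") {
    return(base + rowSums(ifelse(Y > 0, Y * log(mu), 0)))
  }
  ap <- aux$alphaPlus
  if (is.null(ap) || ap <= 0) stop("aux$alphaPlus must be a positive scalar")
  if (family == "dm") {
    a <- ap * mu
    return(base + lgamma(ap) - lgamma(ap + n) +
             rowSums(lgamma(a + Y) - lgamma(a)))
  }
  p <- aux$p
  wt <- aux$wtilde
  if (is.null(p) || is.null(wt)) stop("aux must supply p and wtilde")
  if (family == "fdm") {
    if (length(wt) != 1) stop("fdm uses a single common wtilde")
    wt <- rep(wt, D)
  }
  vapply(seq_len(nrow(Y)), function(i) {
    mp <- efdmMeanParams(mu = mu[i, ], alphaPlus = ap, p = p, wtilde = wt)
    defdm(Y[i, ], mp, log = TRUE)
  }, numeric(1))
}
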