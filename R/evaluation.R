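#' Posterior-predictive count draws
#'
#' For a thinned subsample of posterior draws, counts are re-simulated at
#' each sample's covariates and observed read total under the fitted family.
#'
#' @param fit an [EFDMFit-class].
#' @param data the [EFDMExperiment-class] the model was fitted to (or new
#'   data with the same covariates).
#' @param nRep number of predictive replicates (posterior draws used).
#' @param seed integer seed.
#' @return integer array of dimension nRep x N x D.
#' @export
posteriorPredictive <- function(fit, data, nRep = 100, seed = 1) {
  stopifnot(nRep >= 1)
  set.seed(seed)
  Y <- countMatrix(data)
  X <- covariateMatrix(data)
  N <- nrow(Y); D <- ncol(Y)
  totals <- rowSums(Y)
  draws <- posteriorDraws(fit)
  S <- nrow(draws)
  pick <- if (S <= nRep) rep_len(seq_len(S), nRep)
          else round(seq(1, S, length.out = nRep))
  K1 <- length(fit@covariates)
  bcols <- grep("^beta\\[", colnames(draws))
  out <- array(0L, c(nRep, N, D))
  for (s in seq_len(nRep)) {
    th <- draws[pick[s], ]
    coeffs <- matrix(th[bcols], D - 1, K1, byrow = TRUE)
    mu <- logitLinkMean(coeffs, X, fit@baseline)
    aux <- .auxFromDraw(th, fit@family, D)
    out[s, , ] <- .sampleFamily(fit@family, mu, totals, aux$alphaPlus,
                                aux$p, aux$wtilde)
  }
  out
}

.auxFromDraw <- function(th, family, D) {
  list(alphaPlus = if (family == "multinomial") NULL else unname(th["alphaPlus"]),
       p = if (family %in% c("fdm", "efdm"))
             unname(th[paste0("p[", seq_len(D), "]")]) else NULL,
       wtilde = if (family == "efdm")
                  unname(th[paste0("wtilde[", seq_len(D), "]")])
                else if (family == "fdm") rep(unname(th["wtilde"]), D)
                else NULL)
}

#' Zero-handling confusion metrics
#'
#' A cell is predicted zero when its posterior-predictive probability of
#' being zero exceeds `zeroRule`. Zeros are the positive class, so
#' sensitivity is the fraction of observed zeros that are predicted zero and
#' specificity the fraction of observed positives predicted positive; PPV and
#' NPV are the matching predictive values and accuracy the overall fraction
#' of correct cells.
#'
#' @param observed N x D observed count matrix.
#' @param predictive nRep x N x D array from [posteriorPredictive()].
#' @param zeroRule probability threshold for calling a predicted zero.
#' @return list with the five metrics and the confusion counts
#'   (`tp`, `fp`, `fn`, `tn`; zeros positive).
#' @export
zeroMetrics <- function(observed, predictive, zeroRule = 0.5) {
  observed <- as.matrix(observed)
  stopifnot(length(dim(predictive)) == 3,
            dim(predictive)[2] == nrow(observed),
            dim(predictive)[3] == ncol(observed))
  pZero <- apply(predictive == 0, c(2, 3), mean)
  predZero <- pZero > zeroRule
  obsZero <- observed == 0
  tp <- sum(predZero & obsZero)
  fp <- sum(predZero & !obsZero)
  fn <- sum(!predZero & obsZero)
  tn <- sum(!predZero & !obsZero)
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Kullback-Leibler divergence of predicted from observed compositions
#'
#' Mean over samples of KL(observed proportions || posterior-predictive mean
#' proportions), with additive smoothing 1/(2 n_i) applied to both arguments
#' (then renormalized) so that observed or predicted zeros stay finite.
#'
#' @param observed N x D observed count matrix.
#' @param predictive nRep x N x D predictive array.
#' @return nonnegative scalar; 0 iff the smoothed distributions coincide.
#' @export
klDivergence <- function(observed, predictive) {
  observed <- as.matrix(observed)
  stopifnot(length(dim(predictive)) == 3,
            dim(predictive)[2] == nrow(observed),
            dim(predictive)[3] == ncol(observed))
  n <- rowSums(observed)
  predMean <- apply(predictive, c(2, 3), mean)
  kl <- vapply(seq_len(nrow(observed)), function(i) {
    eps <- 1 / (2 * n[i])
    po <- observed[i, ] / n[i] + eps; po <- po / sum(po)
    pp <- predMean[i, ] / sum(predMean[i, ]) + eps; pp <- pp / sum(pp)
    sum(po * log(po / pp))
  }, numeric(1))
  mean(kl)
}

#' Posterior-averaged moment set of a fitted model
#'
#' Evaluates the model-implied moments at the covariate profile `x` (default:
#' intercept only, i.e. all covariates at their centered mean) for a thinned
#' subsample of posterior draws and averages the moment fields across draws.
#' This is how correlation structure is summarized from a fit.
#'
#' @param fit an [EFDMFit-class] with family "dm", "fdm" or "efdm".
#' @param size count total n at which count-level moments are reported.
#' @param x covariate vector (length K+1 including intercept).
#' @param nDraws number of posterior draws to average over.
#' @return an [EFDMMoments-class] with posterior-mean fields.
#' @export
fittedMoments <- function(fit, size, x = NULL, nDraws = 200) {
  if (fit@family == "multinomial")
    stop("the multinomial has no latent composition; no class correlations")
  draws <- posteriorDraws(fit)
  D <- length(fit@taxa)
  K1 <- length(fit@covariates)
  if (is.null(x)) x <- c(1, rep(0, K1 - 1))
  S <- nrow(draws)
  pick <- if (S <= nDraws) seq_len(S) else round(seq(1, S, length.out = nDraws))
  bcols <- grep("^beta\\[", colnames(draws))
  acc <- NULL
  for (s in pick) {
    th <- draws[s, ]
    coeffs <- matrix(th[bcols], D - 1, K1, byrow = TRUE)
    mu <- as.numeric(logitLinkMean(coeffs, x, fit@baseline))
    aux <- .auxFromDraw(th, fit@family, D)
    mp <- if (fit@family == "dm")
      efdmParams(alpha = aux$alphaPlus * mu, tau = rep(1, D), p = mu)
    else efdmMeanParams(mu = mu, alphaPlus = aux$alphaPlus, p = aux$p,
                        wtilde = aux$wtilde)
    m <- efdmMoments(mp, size, taxa = fit@taxa)
    if (is.null(acc)) {
      acc <- m
    } else {
      acc@mean <- acc@mean + m@mean
      acc@cov <- acc@cov + m@cov
      acc@nvar <- acc@nvar + m@nvar
      acc@intraclass <- acc@intraclass + m@intraclass
      acc@interclass <- acc@interclass + m@interclass
    }
  }
  k <- length(pick)
  acc@mean <- acc@mean / k; acc@cov <- acc@cov / k
  acc@nvar <- acc@nvar / k; acc@intraclass <- acc@intraclass / k
  acc@interclass <- acc@interclass / k
  acc
}

#' Taxa correlation network from interclass correlations
#'
#' Edges for every taxon pair whose interclass correlation is positive
#' (co-occurrence) or below the negative display threshold (co-absence);
#' weak negative correlations are suppressed for readability since the
#' sum constraint makes mild negative dependence ubiquitous.
#'
#' @param moments an [EFDMMoments-class].
#' @param negThreshold negative display threshold (edges with correlation
#'   below it are kept).
#' @param labels optional taxon labels.
#' @return data.frame (source, target, weight, sign) ordered by pair index;
#'   TSV-ready.
#' @export
correlationNetwork <- function(moments, negThreshold = -0.05, labels = NULL) {
  ic <- moments@interclass
  D <- nrow(ic)
  if (is.null(labels)) {
    labels <- rownames(ic)
    if (is.null(labels)) labels <- paste0("taxon", seq_len(D))
  }
  src <- tgt <- character(0); w <- numeric(0)
  for (r in seq_len(D - 1)) for (s in (r + 1):D) {
    val <- ic[r, s]
    if (is.na(val)) next
    if (val > 0 || val < negThreshold) {
      src <- c(src, labels[r]); tgt <- c(tgt, labels[s]); w <- c(w, val)
    }
  }
  data.frame(source = src, target = tgt, weight = w,
             sign = ifelse(w > 0, "positive", "negative"))
}

#' Per-taxon class-correlation table
#'
#' @param moments an [EFDMMoments-class].
#' @param labels optional taxon labels.
#' @return list with `perTaxon` (taxon, intraclass correlation, normalized
#'   variance) and the full `interclass` matrix.
#' @export
classCorrelationTable <- function(moments, labels = NULL) {
  D <- length(moments@intraclass)
  if (is.null(labels)) {
    labels <- names(moments@intraclass)
    if (is.null(labels)) labels <- paste0("taxon", seq_len(D))
  }
  ic <- moments@interclass
  dimnames(ic) <- list(labels, labels)
  list(perTaxon = data.frame(taxon = labels,
                             intraclass = unname(moments@intraclass),
                             nvar = unname(moments@nvar)),
       interclass = ic)
}
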