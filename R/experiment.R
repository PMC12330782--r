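#' Build an EFDMExperiment from counts and covariates
#'
#' @param counts samples-by-taxa matrix of nonnegative integer counts with
#'   taxon names as column names (the stored assay follows the
#'   feature-by-sample orientation).
#' @param covariates optional data.frame or matrix of per-sample covariates
#'   (quantitative and/or 0/1 dummies), rows aligned with `counts`. May be
#'   NULL for covariate-free models.
#' @param standardize logical; center and scale quantitative covariate
#'   columns (dummies are left untouched). Standardization happens here, at
#'   construction, never inside likelihood evaluations.
#' @return an [EFDMExperiment-class] object.
#' @examples
#' y <- matrix(c(3, 1, 6, 2, 4, 4), 2, 3,
#'             dimnames = list(NULL, c("taxA", "taxB", "taxC")))
#' efdmExperiment(y, data.frame(x1 = c(-1, 1)), standardize = FALSE)
#' @export
efdmExperiment <- function(counts, covariates = NULL, standardize = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0))
    stop("samples with zero total reads are not representable")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  cd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(counts))
      stop("covariates must have one row per sample")
    for (j in names(covariates)) {
      v <- covariates[[j]]
      if (!is.numeric(v)) stop("covariate '", j, "' is not numeric")
      isDummy <- all(v %in% c(0, 1))
      if (standardize && !isDummy) {
        s <- sd(v)
        if (s == 0) stop("covariate '", j, "' has zero variance")
        v <- (v - mean(v)) / s
      }
      covariates[[j]] <- v
    }
    cd <- S4Vectors::DataFrame(covariates, row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)), colData = cd)
  new("EFDMExperiment", se)
}

#' Samples-by-taxa count matrix of an experiment
#' @param x an [EFDMExperiment-class].
#' @return N x D numeric matrix (samples in rows).
#' @export
countMatrix <- function(x) {
  t(SummarizedExperiment::assay(x, "counts"))
}

#' Model matrix of an experiment (leading intercept column)
#' @param x an [EFDMExperiment-class].
#' @return N x (K+1) numeric matrix; first column is the intercept.
#' @export
covariateMatrix <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  X <- cbind(`(Intercept)` = rep(1, ncol(x)))
  if (ncol(cd) > 0) X <- cbind(X, as.matrix(cd))
  rownames(X) <- colnames(x)
  X
}

#' Per-sample read totals
#' @param x an [EFDMExperiment-class].
#' @return integer vector of row sums of the count table.
#' @export
sampleTotals <- function(x) {
  colSums(SummarizedExperiment::assay(x, "counts"))
}

#' Taxon names of an experiment
#' @param x an [EFDMExperiment-class].
#' @return character vector of length D.
#' @export
taxonNames <- function(x) rownames(x)
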