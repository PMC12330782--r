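#' Read a delimited count table
#'
#' Expects delimited text with sample IDs in the first column and taxon
#' names in the header. Cells must be nonnegative integers; offending cells
#' are reported by sample and taxon.
#'
#' @param path file path (tab- or comma-delimited; sniffed from the header).
#' @return samples-by-taxa integer matrix with dimnames.
#' @export
readCounts <- function(path) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(!is.finite(m[, j]) | m[, j] < 0 | m[, j] != round(m[, j]))
    if (length(bad))
      stop("invalid count at sample '", ids[bad[1]], "', taxon '",
           colnames(m)[j], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (any(rowSums(m) == 0))
    stop("samples with zero total reads: ",
         paste(ids[rowSums(m) == 0], collapse = ", "))
  m
}

#' Read a covariate table aligned to a count table
#'
#' @param path delimited text keyed by sample ID in the first column.
#' @param sampleIDs sample IDs (e.g. rownames of the count matrix) the rows
#'   must align to; alignment errors list the offending IDs.
#' @param standardize center/scale quantitative columns (0/1 dummies are
#'   left untouched).
#' @return data.frame of covariates in `sampleIDs` order.
#' @export
readCovariates <- function(path, sampleIDs = NULL, standardize = TRUE) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  if (!is.null(sampleIDs)) {
    missing <- setdiff(sampleIDs, ids)
    extra <- setdiff(ids, sampleIDs)
    if (length(missing) || length(extra))
      stop("sample IDs do not align; missing: [",
           paste(missing, collapse = ", "), "] unmatched: [",
           paste(extra, collapse = ", "), "]")
    df <- df[sampleIDs, , drop = FALSE]
  }
  for (j in names(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) stop("covariate '", j, "' is not numeric")
    if (standardize && !all(v %in% c(0, 1))) {
      s <- sd(v)
      if (s == 0) stop("covariate '", j, "' has zero variance")
      df[[j]] <- (v - mean(v)) / s
    }
  }
  df
}

.sniffSep <- function(path) {
  hdr <- readLines(path, n = 1)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Write a samples-by-taxa count matrix as TSV
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist a fitted posterior
#'
#' Writes the constrained-scale draws as CSV, a posterior summary CSV, and a
#' JSON diagnostics sidecar (seed, family, acceptance, R-hat, ESS and a
#' digest of the configuration) into a directory.
#'
#' @param fit an [EFDMFit-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writePosterior <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drawsPath <- file.path(dir, "draws.csv")
  utils::write.csv(as.data.frame(posteriorDraws(fit)), drawsPath,
                   row.names = FALSE)
  sumPath <- file.path(dir, "summary.csv")
  utils::write.csv(posteriorSummary(fit), sumPath, row.names = FALSE)
  d <- diagnostics(fit)
  cfg <- fit@config
  digest <- sum(utf8ToInt(paste(
    fit@family, fit@baseline, d$seed,
    paste(unlist(cfg$priors), collapse = ","),
    paste(unlist(cfg$mcmc), collapse = ","), collapse = "|")))
  side <- list(family = fit@family, baseline = fit@baseline,
               seed = d$seed, chains = d$chains,
               drawsPerChain = d$drawsPerChain,
               acceptRate = d$acceptRate,
               maxRhat = max(d$rhat, na.rm = TRUE),
               minESS = min(d$ess, na.rm = TRUE),
               configDigest = digest)
  diagPath <- file.path(dir, "diagnostics.json")
  jsonlite::write_json(side, diagPath, auto_unbox = TRUE, digits = NA)
  invisible(c(drawsPath, sumPath, diagPath))
}
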