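# Quality control: call-rate filtering, mean imputation, complete cases.

#' Per-SNP call rate
#'
#' Fraction of individuals with an observed (non-missing) genotype at each
#' SNP of a block.
#'
#' @param block A `genotype_block`.
#' @return Numeric vector in \[0, 1\], one entry per SNP.
#' @export
call_rate <- function(block) {
  colMeans(!block_missing(block))
}

#' Call-rate filter mask
#'
#' A SNP is kept iff its call rate is at least `threshold`; the boundary is
#' kept (a 95% call rate passes the default 0.95 filter).
#'
#' @param rates Call-rate vector from [call_rate()].
#' @param threshold Minimum call rate, default 0.95.
#' @return Logical keep mask.
#' @export
filter_by_call_rate <- function(rates, threshold = 0.95) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  rates >= threshold
}

#' Build a QC report table
#'
#' @param snp_ids SNP identifiers.
#' @param rates Call rates.
#' @param threshold Call-rate threshold used.
#' @return A `qc_report` data frame with columns snp_id, call_rate, kept, and
#'   attributes `threshold` and `n_removed`.
#' @export
qc_report <- function(snp_ids, rates, threshold = 0.95) {
  keep <- filter_by_call_rate(rates, threshold)
  structure(data.frame(snp_id = snp_ids, call_rate = rates, kept = keep,
                       stringsAsFactors = FALSE, row.names = NULL),
            threshold = threshold, n_removed = sum(!keep),
            class = c("qc_report", "data.frame"))
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-impute missing genotypes
#'
#' Replaces every missing entry by that SNP's mean over the observed
#' individuals; observed entries are untouched, so per-SNP observed means are
#' preserved. SNPs with no observed value at all must be removed first (they
#' carry no information and have no mean).
#'
#' @param block A `genotype_block`.
#' @return A `genotype_block` with no missing entries.
#' @export
mean_impute <- function(block) {
  miss <- block_missing(block)
  if (!any(miss)) return(block)
  allmiss <- colSums(!miss) == 0L
  if (any(allmiss))
    stop("SNP(s) with no observed genotypes: ",
         paste(utils::head(block$snp_ids[allmiss], 5), collapse = ", "),
         "; filter by call rate first")
  d <- block$doses
  d[miss] <- NA_real_
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  genotype_block(d, snp_offset = block$snp_offset, snp_ids = block$snp_ids,
                 missing_code = NA_real_)
}

#' Indices of fully observed individuals
#'
#' Individuals with a missing phenotype or covariate are removed from the
#' whole analysis; every downstream input (including genotype blocks) is
#' subset by the returned indices.
#'
#' @param y Phenotype vector.
#' @param X Optional covariate matrix with the same number of rows.
#' @return Integer indices of rows with no missing value.
#' @export
complete_cases <- function(y, X = NULL) {
  ok <- !is.na(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != length(y)) stop("y and X have different numbers of rows")
    ok <- ok & rowSums(is.na(X)) == 0L
  }
  idx <- which(ok)
  if (!length(idx)) stop("no individuals with complete phenotype/covariates")
  idx
}
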