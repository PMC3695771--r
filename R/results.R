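# Per-SNP association result table.

#' Assemble an association result table
#'
#' One row per SNP with effect estimate, standard error, Wald statistic,
#' base-10 log p-value and a status flag. `log10_p` is the authoritative
#' p-value output; the linear-scale `p = 10^log10_p` is reported for
#' convenience and may underflow to 0 for extreme statistics. Rows whose
#' status is not `"ok"` carry `NA` estimates.
#'
#' @param snp_id Character vector of SNP identifiers.
#' @param n_used Number of analyzed individuals.
#' @param beta,se Effect estimate (per dose unit) and its standard error.
#' @param log10_p Base-10 log two-sided p-value (non-positive).
#' @param status One of `"ok"`, `"monomorphic"`, `"failed"` per SNP.
#' @param odds_ratio Optional `exp(beta)` column (logistic results).
#' @return An `assoc_result` data frame.
#' @export
assoc_result <- function(snp_id, n_used, beta, se, log10_p, status,
                         odds_ratio = NULL) {
  bad <- status != "ok"
  beta[bad] <- NA_real_; se[bad] <- NA_real_; log10_p[bad] <- NA_real_
  out <- data.frame(snp_id = as.character(snp_id),
                    n_used = as.integer(n_used),
                    beta = beta, se = se, stat = beta / se,
                    log10_p = log10_p, p = 10^log10_p,
                    status = status, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(odds_ratio)) {
    odds_ratio[bad] <- NA_real_
    out$odds_ratio <- odds_ratio
  }
  structure(out, class = c("assoc_result", "data.frame"))
}

#' Write association results as TSV
#'
#' Prepends `#`-prefixed header lines recording the package version and any
#' supplied run descriptors (config hash, seed), so a results file is
#' self-describing and byte-reproducible for a fixed config and seed.
#'
#' @param results An `assoc_result` data frame.
#' @param path Output file.
#' @param run_info Optional named character vector written into the header.
#' @export
write_results_tsv <- function(results, path, run_info = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("semigwas"))
  writeLines(sprintf("# semigwas %s", ver), con)
  if (!is.null(run_info))
    writeLines(sprintf("# %s: %s", names(run_info), run_info), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results_tsv()]
#' @param path Results file.
#' @return Data frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
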