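# End-to-end association scan over a SNP-major store.
#
# Pipeline per block: read -> call-rate filter -> mean imputation ->
# residualize against the null context -> block association. The null
# context (covariate factorization, residualized phenotype or null logistic
# fit) is built once and reused for every block, so the per-block work is a
# handful of dense matrix products. Memory is bounded by
# block_size x n_individuals.

read_id_table <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(what, " file '", x, "' not found")
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  }
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop(what, " table needs an ID column plus value column(s)")
  x
}

# reorder a table's value columns to the store's individual order
align_to_store <- function(tab, individual_ids, what) {
  ids <- as.character(tab[[1]])
  pos <- match(individual_ids, ids)
  if (anyNA(pos)) {
    miss <- utils::head(individual_ids[is.na(pos)], 5)
    stop(what, " table is missing store individual(s): ",
         paste(miss, collapse = ", "))
  }
  tab[pos, -1, drop = FALSE]
}

#' Run a full association scan
#'
#' Streams the store in SNP blocks and computes per-SNP effect, standard
#' error, Wald statistic and log10 p-value with the semi-parallel engines:
#' exact least squares for `model = "linear"`, the one-step null-weight
#' update for `model = "logistic"`. Individuals with missing phenotype or
#' covariates are excluded from the whole analysis; SNPs below the
#' call-rate threshold are dropped and the rest are mean-imputed.
#'
#' Throughput is reported to the message stream in Msips (millions of
#' SNP-individual pairs per second); it is informational only and depends
#' on the machine.
#'
#' @param store_path Genotype store directory.
#' @param phenotype TSV path or data frame: first column individual ID,
#'   second the phenotype (0/1 for logistic).
#' @param covariates Optional TSV path or data frame: first column ID,
#'   remaining columns covariates (no intercept column needed).
#' @param model `"linear"` or `"logistic"`.
#' @param block_size SNPs per block.
#' @param call_rate_threshold Minimum call rate for a SNP to be tested.
#' @param pvalue_reference `"normal"` (default) or `"student"` (linear
#'   model only).
#' @param refit_top_log10p For logistic scans: SNPs with
#'   `log10_p < -refit_top_log10p` are re-fitted by fully iterated maximum
#'   likelihood and their estimates replaced (`status` becomes `"refit"`).
#' @return An `assoc_scan` list: `results` (an `assoc_result` table for the
#'   SNPs passing QC), `qc` (a `qc_report` for all SNPs), `n_used`, `msips`.
#' @export
assoc_scan <- function(store_path, phenotype, covariates = NULL,
                       model = c("linear", "logistic"),
                       block_size = 1000L, call_rate_threshold = 0.95,
                       pvalue_reference = c("normal", "student"),
                       refit_top_log10p = NULL) {
  model <- match.arg(model)
  pvalue_reference <- match.arg(pvalue_reference)
  meta <- read_store_meta(store_path)
  ptab <- read_id_table(phenotype, "phenotype")
  y_all <- as.numeric(align_to_store(ptab, meta$individual_ids, "phenotype")[[1]])
  X_all <- NULL
  if (!is.null(covariates)) {
    ctab <- read_id_table(covariates, "covariate")
    X_all <- as.matrix(align_to_store(ctab, meta$individual_ids, "covariate"))
    storage.mode(X_all) <- "double"
  }
  cc <- complete_cases(y_all, X_all)
  y <- y_all[cc]
  X <- if (is.null(X_all)) NULL else X_all[cc, , drop = FALSE]
  t0 <- proc.time()[["elapsed"]]
  ctx <- if (model == "linear") build_linear_context(y, X)
         else fit_null_logistic(y, X)
  res <- list(); qcl <- list()
  for (r in block_ranges(meta$n_snps, block_size)) {
    blk <- read_block(store_path, r[1], r[2])
    blk <- genotype_block(blk$doses[cc, , drop = FALSE],
                          snp_offset = blk$snp_offset, snp_ids = blk$snp_ids,
                          missing_code = blk$missing_code)
    rates <- call_rate(blk)
    qcl[[length(qcl) + 1L]] <- qc_report(blk$snp_ids, rates,
                                         call_rate_threshold)
    keep <- filter_by_call_rate(rates, call_rate_threshold)
    if (!any(keep)) next
    sub <- genotype_block(blk$doses[, keep, drop = FALSE],
                          snp_offset = blk$snp_offset,
                          snp_ids = blk$snp_ids[keep],
                          missing_code = blk$missing_code)
    sub <- mean_impute(sub)
    if (model == "linear") {
      S_star <- project_block(ctx, sub)
      out <- assoc_linear(ctx, S_star, sub$snp_ids,
                          method = pvalue_reference)
    } else {
      S_star <- weighted_project_block(ctx, sub)
      out <- assoc_logistic(ctx, S_star, sub$snp_ids)
      if (!is.null(refit_top_log10p))
        out <- refit_top_hits(out, y, ctx$X, sub$doses, refit_top_log10p)
    }
    res[[length(res) + 1L]] <- out
    message(sprintf("block [%d, %d): %d/%d SNPs tested", r[1], r[2],
                    sum(keep), length(keep)))
  }
  results <- do.call(rbind, res)
  qc <- do.call(rbind, qcl)
  if (is.null(results)) stop("no SNPs passed the call-rate filter")
  elapsed <- proc.time()[["elapsed"]] - t0
  msips <- length(cc) * nrow(results) / max(elapsed, 1e-9) / 1e6
  message(sprintf("scan: %d SNPs x %d individuals in %.2f s (%.1f Msips, informational)",
                  nrow(results), length(cc), elapsed, msips))
  structure(list(results = results, qc = qc, n_used = length(cc),
                 msips = msips),
            class = "assoc_scan")
}

# replace one-step estimates of the most significant SNPs by the fully
# iterated ML fit
refit_top_hits <- function(out, y, X, doses, refit_top_log10p) {
  hits <- which(!is.na(out$log10_p) & out$log10_p < -abs(refit_top_log10p))
  for (j in hits) {
    fit <- tryCatch(
      logistic_ml_per_snp(y, X, doses[, j]),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- length(fit$coefficients)
    out$beta[j] <- fit$coefficients[p]
    out$se[j] <- fit$se[p]
    out$stat[j] <- out$beta[j] / out$se[j]
    out$log10_p[j] <- log10_pvalue_twosided(out$stat[j])
    out$p[j] <- 10^out$log10_p[j]
    out$odds_ratio[j] <- exp(out$beta[j])
    out$status[j] <- "refit"
  }
  out
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("<assoc_scan> %d SNPs tested, %d individuals used\n",
              nrow(x$results), x$n_used))
  top <- x$results[order(x$results$log10_p), ]
  cat("strongest associations:\n")
  print(utils::head(top, 5), row.names = FALSE)
  invisible(x)
}
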