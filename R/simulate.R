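# Synthetic genotypes, traits and missingness, and the odds-ratio bias
# study characterizing the one-step logistic approximation.

#' Simulate a genotype block
#'
#' `model = "uniform_dose"` draws doses Uniform(0, 2), emulating imputed
#' dosage data with maximal dose variability; `model = "binomial"` draws
#' hard allele counts Binomial(2, maf) per SNP.
#'
#' @param n,m Numbers of individuals and SNPs.
#' @param seed Optional RNG seed.
#' @param model `"uniform_dose"` (default) or `"binomial"`.
#' @param maf Minor-allele frequency (scalar or per SNP) for the binomial
#'   model; if `NULL`, drawn Uniform(0.05, 0.5) per SNP.
#' @return A complete `genotype_block`.
#' @export
simulate_genotypes <- function(n, m, seed = NULL,
                               model = c("uniform_dose", "binomial"),
                               maf = NULL) {
  model <- match.arg(model)
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  doses <- switch(model,
    uniform_dose = matrix(stats::runif(n * m, 0, 2), n, m),
    binomial = {
      if (is.null(maf)) maf <- stats::runif(m, 0.05, 0.5)
      maf <- rep_len(maf, m)
      matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    })
  genotype_block(doses)
}

#' Simulate a quantitative-trait study
#'
#' Phenotype and covariates are independent standard normal draws (a null
#' model with no genetic effect) unless `effects` injects `beta * s` terms
#' for chosen SNPs.
#'
#' @param n,m,k Individuals, SNPs, covariates (excluding intercept).
#' @param seed Optional RNG seed.
#' @param effects Optional numeric vector of effect sizes named/indexed by
#'   SNP column, added to `y`.
#' @param model Genotype model passed to [simulate_genotypes()].
#' @return List with `y`, covariate matrix `X` (intercept first), and
#'   `genotypes` (a `genotype_block`).
#' @export
simulate_quantitative_study <- function(n, m, k = 0L, seed = NULL,
                                        effects = NULL,
                                        model = "uniform_dose") {
  if (n <= k + 2) stop("need n > k + 2")
  if (!is.null(seed)) set.seed(seed)
  genotypes <- simulate_genotypes(n, m, model = model)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (k > 0) {
    Z <- matrix(stats::rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("cov_", seq_len(k))))
    X <- cbind(X, Z)
  }
  y <- stats::rnorm(n)
  if (!is.null(effects)) {
    j <- if (!is.null(names(effects))) match(names(effects), genotypes$snp_ids)
         else seq_along(effects)
    if (anyNA(j)) stop("effects name a SNP absent from the simulated block")
    y <- y + drop(genotypes$doses[, j, drop = FALSE] %*% unname(effects))
  }
  list(y = y, X = X, genotypes = genotypes)
}

#' Simulate a binary trait from a dose vector
#'
#' `y_i ~ Bernoulli(expit(beta0 + beta1 * dose_i))`.
#'
#' @param dose Dose vector.
#' @param beta0 Intercept (log odds at dose 0).
#' @param beta1 Log odds ratio per dose unit.
#' @param seed Optional RNG seed.
#' @return Binary 0/1 vector.
#' @export
simulate_binary_trait <- function(dose, beta0 = 0, beta1 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(length(dose), 1L, stats::plogis(beta0 + beta1 * dose))
}

#' Inject missingness into a genotype block
#'
#' Each entry is independently set to missing with probability
#' `1 - call_rate`.
#'
#' @param block A `genotype_block`.
#' @param call_rate Probability an entry stays observed, in (0, 1].
#' @param seed Optional RNG seed.
#' @return A `genotype_block` with `missing_code = NA`.
#' @export
inject_missing <- function(block, call_rate, seed = NULL) {
  if (call_rate <= 0 || call_rate > 1) stop("call_rate must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- block$doses
  if (!is.na(block$missing_code)) d[d == block$missing_code] <- NA_real_
  drop_mask <- matrix(stats::runif(length(d)) > call_rate, nrow(d), ncol(d))
  d[drop_mask] <- NA_real_
  genotype_block(d, snp_offset = block$snp_offset, snp_ids = block$snp_ids,
                 missing_code = NA_real_)
}

#' Odds-ratio bias study for the one-step logistic estimator
#'
#' Replicates the accuracy experiment for the one-step approximation: per
#' replicate a true odds ratio is drawn uniformly on \[or_low, or_high\]
#' (on the OR scale), doses are Uniform(0, 2), and a binary trait is drawn
#' from `logit p = beta0 + log(OR) * dose`. The fully iterated ML fit (via
#' `stats::glm.fit`) and the one-step estimate from the intercept-only null
#' are recorded together with their Wald log10 p-values, and the relative OR
#' difference `(OR_ml - OR_onestep) / OR_ml` is smoothed against the
#' ML-estimated OR with a loess curve (span 0.5 by default).
#'
#' @param n_models Number of simulated models.
#' @param n Individuals per replicate.
#' @param or_low,or_high Range of the true odds ratio.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param beta0 Intercept of the simulated model.
#' @param span Loess span for the smoothed bias curve.
#' @return An `or_bias_study` list: `records` (one row per kept replicate:
#'   true_or, or_ml, or_onestep, rel_diff, log10p_ml, log10p_onestep),
#'   `n_dropped` (replicates lost to separation/non-convergence), and
#'   `curve`, a function evaluating the smoothed rel_diff at given OR values.
#' @export
or_bias_study <- function(n_models = 1000L, n = 2000L, or_low = 1,
                          or_high = 5, seed = NULL, beta0 = 0, span = 0.5) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_models, replace = TRUE)
  rows <- vector("list", n_models)
  dropped <- 0L
  for (r in seq_len(n_models)) {
    set.seed(rep_seeds[r])
    true_or <- stats::runif(1, or_low, or_high)
    dose <- stats::runif(n, 0, 2)
    y <- simulate_binary_trait(dose, beta0 = beta0, beta1 = log(true_or))
    A <- cbind(1, dose)
    ml <- tryCatch(
      suppressWarnings(stats::glm.fit(A, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(ml) || !ml$converged || ml$boundary) { dropped <- dropped + 1L; next }
    wml <- ml$weights
    cov_ml <- tryCatch(solve(crossprod(A * sqrt(wml))), error = function(e) NULL)
    if (is.null(cov_ml)) { dropped <- dropped + 1L; next }
    beta_ml <- ml$coefficients[2]
    se_ml <- sqrt(cov_ml[2, 2])
    os <- assoc_logistic_nocov(y, matrix(dose, ncol = 1))
    if (os$status != "ok") { dropped <- dropped + 1L; next }
    rows[[r]] <- data.frame(
      true_or = true_or,
      or_ml = exp(beta_ml),
      or_onestep = os$odds_ratio,
      log10p_ml = log10_pvalue_twosided(beta_ml / se_ml),
      log10p_onestep = os$log10_p)
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  records$rel_diff <- (records$or_ml - records$or_onestep) / records$or_ml
  if (dropped > 0)
    message("or_bias_study: dropped ", dropped, " replicate(s)")
  lo <- stats::loess(rel_diff ~ or_ml, data = records, span = span,
                     degree = 2, family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  curve <- function(or) as.numeric(stats::predict(lo, newdata = data.frame(or_ml = or)))
  structure(list(records = records, n_dropped = dropped, curve = curve,
                 loess_fit = lo, span = span, n = n, n_models = n_models),
            class = "or_bias_study")
}

#' Read the smoothed bias curve, in percent
#'
#' @param study An `or_bias_study`.
#' @param at OR values at which to evaluate (default the reference points
#'   1.33, 3 and 5).
#' @param se If `TRUE`, return a data frame with the smoother's pointwise
#'   standard errors (in percent) alongside the readings.
#' @return Named numeric vector of smoothed relative OR underestimation in
#'   percent, or a data frame when `se = TRUE`.
#' @export
bias_curve_at <- function(study, at = c(1.33, 3, 5), se = FALSE) {
  if (!se) return(stats::setNames(100 * study$curve(at), format(at)))
  pr <- stats::predict(study$loess_fit, newdata = data.frame(or_ml = at),
                       se = TRUE)
  data.frame(or = at, rel_diff_pct = 100 * as.numeric(pr$fit),
             se_pct = 100 * as.numeric(pr$se.fit))
}

#' @export
print.or_bias_study <- function(x, ...) {
  cat(sprintf("<or_bias_study> %d replicates kept (%d dropped), n = %d per replicate\n",
              nrow(x$records), x$n_dropped, x$n))
  v <- bias_curve_at(x)
  cat("smoothed relative OR underestimation (%):\n")
  print(round(v, 3))
  invisible(x)
}
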