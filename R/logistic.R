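# Approximate semi-parallel logistic regression.
#
# The covariate-only ("null") model  logit p = X gamma  is fitted once by
# IRLS. Its probabilities p~, weights w~ = p~(1-p~) and working response
#   z = logit(p~) + (y - p~)/w~
# then drive a single weighted least-squares step per SNP:
#   s* = s - X (X'W~X)^-1 X'W~ s,   z* = z - X (X'W~X)^-1 X'W~ z,
#   beta1 = sum(w~ z* s*) / sum(w~ s*^2),   var(beta1) = 1 / sum(w~ s*^2).
# This equals one Fisher-scoring update of the full (X, s) model started at
# (gamma_null, 0): exact for the null weights, approximate for fully
# iterated maximum likelihood. The weight "matrix" is held as a vector and
# only ever used as an elementwise scale.

#' Fit the covariate-only logistic null model
#'
#' Fully iterated IRLS from zero starting coefficients, stopping when the
#' largest coefficient change drops below `tol`. The returned context caches
#' everything the per-SNP one-step update needs: probabilities, weights, the
#' working response and its weighted residualization `z_star` (which does not
#' depend on the SNP), and the weighted factorization of `X`.
#'
#' @param y Binary 0/1 phenotype with both classes present; complete cases.
#' @param X Optional covariate matrix; an intercept is prepended if absent.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Iteration cap.
#' @return A `logistic_null_context`.
#' @export
fit_null_logistic <- function(y, X = NULL, tol = 1e-8, max_iter = 25L) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("phenotype contains missing values; take complete cases first")
  if (!all(y %in% c(0, 1))) stop("logistic phenotype must be coded 0/1")
  if (length(unique(y)) < 2L) stop("phenotype has a single class; cannot fit")
  X <- ensure_intercept(X, n)
  k <- ncol(X) - 1L
  p <- ncol(X)
  gamma <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% gamma)
    prob <- stats::plogis(eta)
    if (any(prob < 1e-10 | prob > 1 - 1e-10))
      stop("null logistic fit did not converge: fitted probabilities at the ",
           "0/1 boundary (quasi-separation)")
    w <- prob * (1 - prob)
    z <- eta + (y - prob) / w
    sw <- sqrt(w)
    qw <- qr(X * sw)
    if (qw$rank < p) stop("covariate matrix is rank deficient in the weighted fit")
    gamma_new <- qr.coef(qw, sw * z)
    if (max(abs(gamma_new - gamma)) < tol) {
      gamma <- gamma_new
      converged <- TRUE
      break
    }
    gamma <- gamma_new
    if (iter >= max_iter)
      stop("null logistic fit did not converge within ", max_iter, " iterations")
  }
  eta <- drop(X %*% gamma)
  prob <- stats::plogis(eta)
  w <- prob * (1 - prob)
  z <- working_response(prob, w, y)
  sw <- sqrt(w)
  qw <- qr(X * sw)
  # economy Q of sqrt(W) X: the W-weighted projection onto span(X) is
  # diag(1/sw) Qw Qw' diag(sw), applied right-to-left (largest temp (k+1) x b)
  Qw <- qr.Q(qw)
  z_star <- z - drop(Qw %*% crossprod(Qw, sw * z)) / sw
  structure(list(X = X, n = n, k = k, gamma_null = gamma,
                 p_tilde = prob, w_tilde = w, z_tilde = z, z_star = z_star,
                 qr_w = qw, Qw = Qw, sqrt_w = sw,
                 converged = converged, iterations = iter),
            class = "logistic_null_context")
}

#' IRLS working response
#'
#' `z_i = logit(p_i) + (y_i - p_i) / w_i` with `w_i = p_i (1 - p_i)`.
#'
#' @param p Fitted probabilities, strictly inside (0, 1).
#' @param w Weights `p * (1 - p)`.
#' @param y Binary response.
#' @return Working response vector.
#' @export
working_response <- function(p, w, y) {
  if (any(w <= 0)) stop("weights must be strictly positive")
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  stats::qlogis(p) + (y - p) / w
}

#' Weighted residualization of a SNP block
#'
#' `S* = S - X (X'W~X)^-1 X'W~ S` under the null-model weights, evaluated
#' right-to-left via the cached weighted QR so the largest intermediate is
#' `(k+1) x b`.
#'
#' @param ctx A `logistic_null_context`.
#' @param block Complete `genotype_block` or dose matrix, rows matching the
#'   context.
#' @return Matrix `S*`.
#' @export
weighted_project_block <- function(ctx, block) {
  S <- dose_matrix(block)
  if (nrow(S) != ctx$n)
    stop("block has ", nrow(S), " rows but context expects ", ctx$n)
  if (anyNA(S)) stop("block contains missing doses; mean_impute first")
  S - (ctx$Qw %*% crossprod(ctx$Qw, ctx$sqrt_w * S)) / ctx$sqrt_w
}

#' Semi-parallel one-step logistic association for a residualized block
#'
#' Per SNP: `beta1 = sum(w~ z* s*) / sum(w~ s*^2)`,
#' `se = 1 / sqrt(sum(w~ s*^2))`, odds ratio `exp(beta1)`, Wald statistic
#' against the normal reference. Computed for the whole block with one
#' matrix-vector product.
#'
#' @param ctx A `logistic_null_context`.
#' @param S_star Matrix from [weighted_project_block()] under the same
#'   context.
#' @param snp_ids SNP identifiers.
#' @return An `assoc_result` data frame including an `odds_ratio` column.
#' @export
assoc_logistic <- function(ctx, S_star, snp_ids = colnames(S_star)) {
  S_star <- as.matrix(S_star)
  if (nrow(S_star) != ctx$n)
    stop("S_star has ", nrow(S_star), " rows but context expects ", ctx$n)
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(ncol(S_star)))
  denom <- colSums(ctx$w_tilde * S_star^2)
  num <- drop(crossprod(S_star, ctx$w_tilde * ctx$z_star))
  mono <- denom <= MONO_EPS * ctx$n
  beta <- ifelse(mono, NA_real_, num / denom)
  se <- 1 / sqrt(denom)
  stat <- beta / se
  log10p <- rep(NA_real_, length(beta))
  ok <- !mono & is.finite(stat)
  log10p[ok] <- log10_pvalue_twosided(stat[ok], method = "normal")
  status <- ifelse(mono, "monomorphic", ifelse(ok, "ok", "failed"))
  assoc_result(snp_ids, ctx$n, beta, se, log10p, status,
               odds_ratio = exp(beta))
}

#' One-step logistic association without covariates
#'
#' The intercept-only null model has constant probabilities
#' `p~ = mean(y)` and constant weights, so the weighted means reduce to
#' arithmetic means:
#' `beta1 = sum(w (z - z_w)(s - s_w)) / (w sum((s - s_w)^2))`.
#' Coincides exactly with [assoc_logistic()] under an intercept-only `X`.
#'
#' @param y Binary 0/1 phenotype, both classes present.
#' @param S Dose matrix or complete `genotype_block`.
#' @param snp_ids SNP identifiers.
#' @return An `assoc_result` data frame with `odds_ratio`.
#' @export
assoc_logistic_nocov <- function(y, S, snp_ids = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("logistic phenotype must be coded 0/1")
  if (length(unique(y)) < 2L) stop("phenotype has a single class; cannot fit")
  S <- dose_matrix(S)
  if (anyNA(S)) stop("block contains missing doses; mean_impute first")
  n <- length(y)
  if (nrow(S) != n) stop("dimension mismatch between y and S")
  if (is.null(snp_ids))
    snp_ids <- if (!is.null(colnames(S))) colnames(S) else paste0("snp_", seq_len(ncol(S)))
  p0 <- mean(y)
  w <- p0 * (1 - p0)                       # constant across individuals
  z <- stats::qlogis(p0) + (y - p0) / w
  zc <- z - mean(z)
  sbar <- colMeans(S)
  css <- colSums(S^2) - n * sbar^2         # sum((s - s_w)^2), s_w = sbar
  num <- w * drop(crossprod(S, zc))        # sum(w (z - z_w)(s - s_w))
  denom <- w * css
  mono <- denom <= MONO_EPS * n
  beta <- ifelse(mono, NA_real_, num / denom)
  se <- 1 / sqrt(denom)
  stat <- beta / se
  log10p <- rep(NA_real_, length(beta))
  ok <- !mono & is.finite(stat)
  log10p[ok] <- log10_pvalue_twosided(stat[ok], method = "normal")
  status <- ifelse(mono, "monomorphic", ifelse(ok, "ok", "failed"))
  assoc_result(snp_ids, n, beta, se, log10p, status, odds_ratio = exp(beta))
}
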