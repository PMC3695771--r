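# Exact semi-parallel linear regression.
#
# For each SNP s the model  y = beta*s + X gamma + eps  is reduced, by
# residualizing y and s against the covariates X (Frisch-Waugh-Lovell), to a
# simple regression through the origin:
#   y* = y - X (X'X)^-1 X'y,   s* = s - X (X'X)^-1 X's,
#   beta = sum(y* s*) / sum(s*^2),
#   RSS  = sum(y*^2) - beta^2 sum(s*^2),  sigma2 = RSS / (n - k - 2),
#   var(beta) = sigma2 / sum(s*^2).
# All per-SNP quantities are computed as one dense matrix product per block,
# never as a loop of model fits, and the projections are evaluated so the
# largest intermediate is (k+1) x b, never n x n.

MONO_EPS <- 1e-12

#' Build the reusable linear null context
#'
#' Factorizes the covariate matrix once and residualizes the phenotype
#' against it; the context is then reused for every SNP block of a scan. The
#' projection uses a QR factorization, never an explicit inverse of `X'X`.
#' If no column of `X` spans the constant vector, an intercept column is
#' prepended.
#'
#' @param y Phenotype vector, complete cases only.
#' @param X Optional covariate matrix (without or with an intercept column).
#' @return A `linear_null_context` with the QR factorization, the
#'   residualized phenotype `y_star` and its cached sum of squares.
#' @export
build_linear_context <- function(y, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("phenotype contains missing values; take complete cases first")
  X <- ensure_intercept(X, n)
  k <- ncol(X) - 1L
  if (n <= k + 2L)
    stop("insufficient sample size: n = ", n, " <= k + 2 = ", k + 2L)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[(qx$rank + 1L):ncol(X)]
    nm <- colnames(X)
    nm <- if (is.null(nm)) paste0("column ", drop) else nm[drop]
    stop("covariate matrix is rank deficient; offending: ",
         paste(nm, collapse = ", "))
  }
  Q <- qr.Q(qx)                  # economy n x (k+1) orthonormal basis of span(X)
  y_star <- y - drop(Q %*% crossprod(Q, y))
  structure(list(X = X, qr = qx, Q = Q, n = n, k = k,
                 y_star = y_star, sum_y_star_sq = sum(y_star^2)),
            class = "linear_null_context")
}

# prepend an intercept unless the constant vector already lies in span(X)
ensure_intercept <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("covariate matrix has ", nrow(X), " rows, expected ", n)
  if (anyNA(X)) stop("covariates contain missing values; take complete cases first")
  r <- qr.resid(qr(X), rep(1, n))
  if (sqrt(sum(r^2)) > 1e-8 * sqrt(n)) {
    X <- cbind(intercept = 1, X)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Residualize a SNP block against the covariates
#'
#' Computes `S* = S - X (X'X)^-1 X'S` through the context's QR factor as
#' `S - Q (Q'S)`; evaluated right-to-left, so the largest intermediate is
#' `(k+1) x b` and no `n x n` matrix ever exists.
#'
#' @param ctx A `linear_null_context`.
#' @param block A complete (imputed) `genotype_block` or dose matrix with
#'   rows matching the context.
#' @return Matrix `S*` of residualized SNP columns.
#' @export
project_block <- function(ctx, block) {
  S <- dose_matrix(block)
  if (nrow(S) != ctx$n)
    stop("block has ", nrow(S), " rows but context expects ", ctx$n)
  if (anyNA(S)) stop("block contains missing doses; mean_impute first")
  S - ctx$Q %*% crossprod(ctx$Q, S)
}

#' Semi-parallel single-SNP linear association for a residualized block
#'
#' All estimates, standard errors and log p-values of the block are computed
#' with two matrix-vector products and vectorized arithmetic. SNPs whose
#' residualized column is numerically zero (monomorphic, or collinear with
#' the covariates) are flagged rather than failing the scan.
#'
#' @param ctx A `linear_null_context`.
#' @param S_star Residualized SNP matrix from [project_block()] under the
#'   same context.
#' @param snp_ids SNP identifiers, one per column.
#' @param method Reference distribution for the Wald statistic: `"normal"`
#'   (default, the large-sample choice) or `"student"` with `n - k - 2`
#'   degrees of freedom.
#' @return An `assoc_result` data frame.
#' @export
assoc_linear <- function(ctx, S_star, snp_ids = colnames(S_star),
                         method = c("normal", "student")) {
  method <- match.arg(method)
  S_star <- as.matrix(S_star)
  if (nrow(S_star) != ctx$n)
    stop("S_star has ", nrow(S_star), " rows but context expects ", ctx$n)
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(ncol(S_star)))
  df <- ctx$n - ctx$k - 2L
  denom <- colSums(S_star^2)
  num <- drop(crossprod(S_star, ctx$y_star))
  mono <- denom <= MONO_EPS * ctx$n
  beta <- ifelse(mono, NA_real_, num / denom)
  rss <- ctx$sum_y_star_sq - beta^2 * denom
  # tiny negatives are roundoff from the cancellation; real negatives flag failure
  failed <- !mono & (rss < -1e-8 * ctx$sum_y_star_sq | !is.finite(beta))
  rss <- pmax(rss, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / denom)
  stat <- beta / se
  ok <- !mono & !failed
  log10p <- rep(NA_real_, length(beta))
  fin <- ok & is.finite(stat)
  log10p[fin] <- log10_pvalue_twosided(stat[fin], method = method, df = df)
  log10p[ok & is.infinite(stat)] <- -Inf   # exact fit: se = 0, p underflows
  status <- rep("ok", length(beta))
  status[failed] <- "failed"
  status[mono] <- "monomorphic"
  assoc_result(snp_ids, ctx$n, beta, se, log10p, status)
}

#' Linear association without covariates, uncentered form
#'
#' With a mean-centered phenotype the slope of `y ~ s` is
#' `sum(y_c * s) / (sum(s^2) - n * mean(s)^2)`; neither centering nor
#' copying of the SNP matrix is needed.
#'
#' @param y Phenotype vector, complete.
#' @param S Dose matrix or complete `genotype_block`.
#' @param snp_ids SNP identifiers.
#' @param method As in [assoc_linear()].
#' @return An `assoc_result` data frame, identical to [assoc_linear()] with
#'   an intercept-only covariate matrix.
#' @export
assoc_linear_nocov <- function(y, S, snp_ids = NULL,
                               method = c("normal", "student")) {
  method <- match.arg(method)
  S <- dose_matrix(S)
  if (anyNA(S)) stop("block contains missing doses; mean_impute first")
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(S) != n) stop("dimension mismatch between y and S")
  if (is.null(snp_ids))
    snp_ids <- if (!is.null(colnames(S))) colnames(S) else paste0("snp_", seq_len(ncol(S)))
  yc <- y - mean(y)
  syy <- sum(yc^2)
  num <- drop(crossprod(S, yc))                 # = sum(yc * (s - sbar))
  denom <- colSums(S^2) - n * colMeans(S)^2     # = sum((s - sbar)^2)
  df <- n - 2L
  mono <- denom <= MONO_EPS * n
  beta <- ifelse(mono, NA_real_, num / denom)
  rss <- pmax(syy - beta^2 * denom, 0)
  se <- sqrt(rss / df / denom)
  stat <- beta / se
  ok <- !mono & is.finite(beta)
  log10p <- rep(NA_real_, length(beta))
  fin <- ok & is.finite(stat)
  log10p[fin] <- log10_pvalue_twosided(stat[fin], method = method, df = df)
  log10p[ok & is.infinite(stat)] <- -Inf
  status <- ifelse(mono, "monomorphic", ifelse(ok, "ok", "failed"))
  assoc_result(snp_ids, n, beta, se, log10p, status)
}

#' Underflow-safe two-sided log10 p-value
#'
#' Evaluates `log10 p = log10 2 + log CDF(-|stat|) / ln 10` with the
#' distribution's log-scale lower-tail routine. The textbook form
#' `2 * (1 - CDF(|stat|))` underflows to exactly 0 for |stat| above ~38
#' (normal); the log-scale form stays finite and strictly monotone far
#' beyond genome-wide significance.
#'
#' @param stat Wald statistic(s), finite.
#' @param method `"normal"` (default) or `"student"`.
#' @param df Degrees of freedom, required for `"student"`.
#' @return `log10` of the two-sided p-value (non-positive), vectorized.
#' @export
log10_pvalue_twosided <- function(stat, method = c("normal", "student"),
                                  df = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(stat))) stop("test statistic must be finite")
  lt <- if (method == "normal") {
    stats::pnorm(-abs(stat), log.p = TRUE)
  } else {
    if (is.null(df) || df <= 0) stop("method 'student' needs df > 0")
    stats::pt(-abs(stat), df = df, log.p = TRUE)
  }
  (log(2) + lt) / log(10)
}
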