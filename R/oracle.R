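# Brute-force per-SNP reference fitters.
#
# These are the slow, textbook computations the block engines are verified
# against: plain normal-equations least squares and a hand-rolled IRLS with
# step-halving. They deliberately share no code path with the engines (no
# residualization, no cached factorizations) and are meant for test-scale
# problems only.

#' Textbook least squares on the augmented design [X s]
#'
#' Normal-equations solve with `sigma2 = RSS / (n - p)`, `p = ncol([X s])`.
#' The SNP coefficient and its standard error (the last entries) are the
#' comparison surface for the semi-parallel linear engine.
#'
#' @param y Phenotype vector.
#' @param X Covariate matrix including the intercept.
#' @param s SNP dose vector.
#' @return An `oracle_fit` list: coefficients, se, rss, df, converged,
#'   iterations.
#' @export
ols_per_snp <- function(y, X, s) {
  A <- cbind(as.matrix(X), snp = as.numeric(s))
  n <- nrow(A); p <- ncol(A)
  if (n <= p) stop("need n > number of coefficients")
  G <- crossprod(A)
  if (rcond(G) < 1e-14) stop("augmented design [X s] is (near) rank deficient")
  Ginv <- solve(G)
  coef <- drop(Ginv %*% crossprod(A, y))
  resid <- y - drop(A %*% coef)
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * diag(Ginv))
  structure(list(coefficients = coef, se = se, rss = rss, df = n - p,
                 converged = TRUE, iterations = 0L),
            class = "oracle_fit")
}

logistic_deviance <- function(y, prob) {
  -2 * sum(y * log(prob) + (1 - y) * log1p(-prob))
}

#' Fully iterated maximum-likelihood logistic fit
#'
#' Hand-rolled IRLS on the augmented design `[X s]` (or `X` alone when `s`
#' is `NULL`), with step-halving whenever a step would increase the
#' deviance. The covariance comes from the inverse Fisher information at
#' convergence.
#'
#' @param y Binary 0/1 response, both classes present.
#' @param X Covariate matrix including the intercept.
#' @param s Optional SNP dose vector appended as the last column.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Iteration cap.
#' @return An `oracle_fit` with coefficients, se, loglik, deviance
#'   trajectory, converged flag and iteration count.
#' @export
logistic_ml_per_snp <- function(y, X, s = NULL, tol = 1e-10, max_iter = 50L) {
  if (length(unique(y)) < 2L) stop("response has a single class")
  A <- as.matrix(X)
  if (!is.null(s)) A <- cbind(A, snp = as.numeric(s))
  n <- nrow(A); p <- ncol(A)
  beta <- rep(0, p)
  prob <- stats::plogis(drop(A %*% beta))
  dev <- logistic_deviance(y, prob)
  dev_trace <- dev
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- prob * (1 - prob)
    if (any(prob < 1e-12 | prob > 1 - 1e-12))
      stop("logistic ML oracle: separation (fitted probabilities at 0/1)")
    info <- crossprod(A, A * w)
    score <- crossprod(A, y - prob)
    step <- drop(solve(info, score))
    # step-halve until the deviance does not increase
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      prob_new <- stats::plogis(drop(A %*% beta_new))
      dev_new <- logistic_deviance(y, prob_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) stop("logistic ML oracle: step-halving failed")
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new; prob <- prob_new; dev <- dev_new
    dev_trace <- c(dev_trace, dev)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("logistic ML oracle did not converge in ", max_iter,
                       " iterations")
  w <- prob * (1 - prob)
  covmat <- solve(crossprod(A, A * w))
  structure(list(coefficients = beta, se = sqrt(diag(covmat)),
                 loglik = -dev / 2, deviance_trace = dev_trace,
                 converged = converged, iterations = iter),
            class = "oracle_fit")
}

#' One Fisher-scoring step of the full logistic model from the null fit
#'
#' Starts the full `[X s]` model at `(gamma_null, 0)` and performs exactly
#' one weighted least-squares update. The SNP coordinate of the result is,
#' by the weighted Frisch-Waugh-Lovell identity, algebraically equal to the
#' semi-parallel one-step estimate; this fitter verifies that identity from
#' the other side.
#'
#' @param y Binary 0/1 response.
#' @param X Covariate matrix including the intercept.
#' @param s SNP dose vector.
#' @param null_fit Converged covariate-only coefficients, or a
#'   `logistic_null_context`.
#' @return An `oracle_fit` with the post-step coefficients and the standard
#'   errors from the starting-weight Fisher information.
#' @export
logistic_one_step_full <- function(y, X, s, null_fit) {
  gamma0 <- if (inherits(null_fit, "logistic_null_context")) null_fit$gamma_null
            else as.numeric(null_fit)
  A <- cbind(as.matrix(X), snp = as.numeric(s))
  start <- c(gamma0, 0)
  eta <- drop(A %*% start)
  prob <- stats::plogis(eta)
  w <- prob * (1 - prob)
  z <- eta + (y - prob) / w
  info <- crossprod(A, A * w)
  beta <- drop(solve(info, crossprod(A, w * z)))
  covmat <- solve(info)
  structure(list(coefficients = beta, se = sqrt(diag(covmat)),
                 converged = TRUE, iterations = 1L),
            class = "oracle_fit")
}
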