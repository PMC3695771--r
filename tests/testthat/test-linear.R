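# Exact semi-parallel linear engine.

make_design <- function(n, k, seed) {
  set.seed(seed)
  X <- if (k > 0) cbind(1, matrix(stats::rnorm(n * k), n, k)) else NULL
  list(X = X, y = stats::rnorm(n),
       S = matrix(stats::runif(n * 25, 0, 2), n, 25))
}

test_that("the null context residualizes the phenotype orthogonally to X", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  ctx0 <- build_linear_context(y)
  expect_equal(ctx0$y_star, y - mean(y))
  d <- make_design(20, 3, seed = 1)
  ctx <- build_linear_context(d$y, d$X)
  expect_lt(max(abs(crossprod(ctx$X, ctx$y_star))),
            1e-10 * sqrt(sum(d$y^2)))
  # phenotype inside span(X) leaves a zero residual
  y_in <- drop(d$X %*% c(1, -2, 0.5, 3))
  expect_lt(max(abs(build_linear_context(y_in, d$X)$y_star)), 1e-10)
})

test_that("degenerate covariate matrices are rejected with informative errors", {
  d <- make_design(20, 2, seed = 2)
  Xdup <- cbind(d$X, dup = d$X[, 2])
  expect_error(build_linear_context(d$y, Xdup), "rank deficient")
  expect_error(build_linear_context(stats::rnorm(5),
                                    cbind(1, matrix(stats::rnorm(20), 5, 4))),
               "insufficient sample")
  # an intercept is added when absent, and left alone when present
  Xno <- matrix(stats::rnorm(20), 20, 1)
  expect_equal(ncol(build_linear_context(d$y, Xno)$X), 2)
  expect_equal(ncol(build_linear_context(d$y, d$X)$X), 3)
})

test_that("block residualization is orthogonal, idempotent, and centers under intercept", {
  d <- make_design(30, 3, seed = 3)
  ctx <- build_linear_context(d$y, d$X)
  S_star <- project_block(ctx, d$S)
  expect_lt(max(abs(crossprod(ctx$X, S_star))), 1e-8 * max(abs(d$S)) * 30)
  expect_equal(project_block(ctx, S_star), S_star, tolerance = 1e-12)
  # intercept-only projection is column centering
  ctx0 <- build_linear_context(d$y)
  expect_equal(project_block(ctx0, d$S), scale(d$S, scale = FALSE),
               ignore_attr = TRUE)
  # constant SNP residualizes to zero when an intercept is present
  expect_lt(max(abs(project_block(ctx, matrix(1.37, 30, 1)))), 1e-12)
  expect_error(project_block(ctx, d$S[1:10, ]), "rows")
})

test_that("semi-parallel estimates match per-SNP least squares across k", {
  for (k in c(0, 2, 5)) {
    d <- make_design(120, k, seed = 10 + k)
    ctx <- build_linear_context(d$y, d$X)
    res <- assoc_linear(ctx, project_block(ctx, d$S))
    for (j in c(1, 7, 25)) {
      o <- ols_per_snp(d$y, ctx$X, d$S[, j])
      p <- length(o$coefficients)
      expect_equal(res$beta[j], unname(o$coefficients[p]), tolerance = 1e-10)
      expect_equal(res$se[j], unname(o$se[p]), tolerance = 1e-10)
    }
  }
})

test_that("the uncentered no-covariate form equals the projected intercept-only fit", {
  d <- make_design(80, 0, seed = 21)
  ctx0 <- build_linear_context(d$y)
  a <- assoc_linear(ctx0, project_block(ctx0, d$S))
  b <- assoc_linear_nocov(d$y, d$S)
  expect_equal(b$beta, a$beta, tolerance = 1e-10)
  expect_equal(b$se, a$se, tolerance = 1e-10)
  expect_equal(b$log10_p, a$log10_p, tolerance = 1e-10)
  # constant phenotype: zero effects
  expect_equal(assoc_linear_nocov(rep(2, 80), d$S)$beta, rep(0, 25))
  # constant SNP: flagged monomorphic, estimates withheld
  mono <- assoc_linear_nocov(d$y, cbind(d$S[, 1], 1.5))
  expect_equal(mono$status, c("ok", "monomorphic"))
  expect_true(is.na(mono$beta[2]))
})

test_that("results are invariant to reparameterizing the covariate space", {
  d <- make_design(60, 4, seed = 31)
  ctx <- build_linear_context(d$y, d$X)
  res <- assoc_linear(ctx, project_block(ctx, d$S))
  set.seed(32)
  Tm <- matrix(stats::rnorm(25), 5, 5)
  while (abs(det(Tm)) < 0.1) Tm <- matrix(stats::rnorm(25), 5, 5)
  ctx2 <- build_linear_context(d$y, d$X %*% Tm)
  res2 <- assoc_linear(ctx2, project_block(ctx2, d$S))
  expect_equal(res2$beta, res$beta, tolerance = 1e-8)
  expect_equal(res2$se, res$se, tolerance = 1e-8)
  expect_equal(res2$log10_p, res$log10_p, tolerance = 1e-8)
})

test_that("association results are independent of the block partition", {
  d <- make_design(50, 2, seed = 41)
  ctx <- build_linear_context(d$y, d$X)
  whole <- assoc_linear(ctx, project_block(ctx, d$S))
  pieces <- lapply(list(1:7, 8:20, 21:25), function(js)
    assoc_linear(ctx, project_block(ctx, d$S[, js, drop = FALSE]),
                 snp_ids = whole$snp_id[js]))
  expect_equal(do.call(rbind, pieces), whole, ignore_attr = TRUE)
})

test_that("a perfect fit reports the exact slope with zero standard error", {
  set.seed(51)
  s <- stats::runif(40, 0, 2)
  ctx0 <- build_linear_context(2 * (s - mean(s)))
  res <- assoc_linear(ctx0, project_block(ctx0, matrix(s, ncol = 1)))
  expect_equal(res$beta, 2, tolerance = 1e-12)
  expect_equal(res$se, 0)
  expect_equal(res$status, "ok")
  expect_equal(res$log10_p, -Inf)
})

test_that("log10 p-values are computed on the log scale and stay finite deep in the tail", {
  expect_equal(log10_pvalue_twosided(0), 0)
  expect_equal(log10_pvalue_twosided(1.959964), log10(0.05), tolerance = 1e-4)
  expect_equal(log10_pvalue_twosided(40), log10p_asymptotic_oracle(40),
               tolerance = 1e-6)
  # textbook 2*(1 - pnorm(t)) underflows to exactly 0 up here; log form does not
  expect_identical(2 * (1 - stats::pnorm(40)), 0)
  expect_true(is.finite(log10_pvalue_twosided(40)))
  # student reference agrees with the textbook formula where it is safe
  expect_equal(log10_pvalue_twosided(2, method = "student", df = 30),
               log10(2 * stats::pt(-2, df = 30)), tolerance = 1e-12)
  expect_error(log10_pvalue_twosided(2, method = "student", df = 0), "df")
  expect_error(log10_pvalue_twosided(Inf), "finite")
  # strict monotonicity in |stat|
  g <- log10_pvalue_twosided(seq(0, 200, by = 0.5))
  expect_true(all(diff(g) < 0))
})
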