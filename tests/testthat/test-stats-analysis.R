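test_that("one-tailed Pearson reproduces t from r and matches cor.test", {
  # published-style r/df pairs recompute to their printed t statistics
  tfun <- function(r, df) r * sqrt(df / (1 - r^2))
  expect_equal(tfun(0.624, 22), 3.748, tolerance = 0.01)
  expect_equal(tfun(0.440, 70), 4.094, tolerance = 0.01)
  expect_equal(tfun(0.343, 85), 3.367, tolerance = 0.01)

  set.seed(8)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  res <- pearson_one_tailed(x, y, "positive")
  ct <- cor.test(x, y, alternative = "greater")
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p_one_tailed, ct$p.value, tolerance = 1e-12)
  expect_equal(res$df, 38)
  expect_equal(res$t_stat, unname(ct$statistic), tolerance = 1e-12)

  resn <- pearson_one_tailed(x, y, "negative")
  expect_equal(resn$p_one_tailed, 1 - res$p_one_tailed, tolerance = 1e-12)
})

test_that("perfect correlations give boundary p-values and constants error", {
  x <- 1:10
  up <- pearson_one_tailed(x, x * 2 + 1, "positive")
  expect_equal(up$r, 1)
  expect_lt(up$p_one_tailed, 1e-12)
  dn <- pearson_one_tailed(x, -x, "positive")
  expect_equal(dn$r, -1)
  expect_gt(dn$p_one_tailed, 1 - 1e-12)
  expect_error(pearson_one_tailed(x, rep(1, 10)), "constant")
})

test_that("Pearson r is invariant to positive affine transforms", {
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30)
  base <- pearson_one_tailed(x, y, "positive")
  tr <- pearson_one_tailed(3 * x + 7, 0.2 * y - 5, "positive")
  expect_equal(tr$r, base$r, tolerance = 1e-12)
  expect_equal(tr$p_one_tailed, base$p_one_tailed, tolerance = 1e-12)
})

test_that("zscore centres, scales, and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(100, 50, 9)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), "constant")
})

simulate_lmm <- function(n_subj, n_per, beta1, sd_u, sd_e, seed) {
  set.seed(seed)
  subject <- rep(sprintf("S%02d", seq_len(n_subj)), each = n_per)
  u <- rep(rnorm(n_subj, 0, sd_u), each = n_per)
  x1 <- rnorm(n_subj * n_per)
  y <- beta1 * x1 + u + rnorm(n_subj * n_per, 0, sd_e)
  tibble::tibble(subject_id = subject, y = y, x1 = x1)
}

test_that("LMM collapses to OLS when there is no subject variation", {
  d <- simulate_lmm(10, 8, 0.5, sd_u = 0, sd_e = 1, seed = 2)
  fit <- random_intercept_lmm(d, "y", "x1")
  expect_equal(fit$subject_variance, 0, tolerance = 1e-8)
  ols <- coef(lm(zscore(d$y) ~ zscore(d$x1)))[["zscore(d$x1)"]]
  expect_equal(unname(fit$betas$beta[fit$betas$term == "x1"]), ols,
               tolerance = 1e-6)
})

test_that("LMM recovers injected random variance and fixed effects", {
  # pure subject shifts: fixed beta ~ 0, subject variance ~ injected share
  d0 <- simulate_lmm(50, 10, 0, sd_u = 1, sd_e = 1, seed = 14)
  f0 <- random_intercept_lmm(d0, "y", "x1")
  expect_lt(abs(unname(f0$betas$beta[f0$betas$term == "x1"])), 0.1)
  # after z-scoring, variances are shares of total ~ 0.5 each
  expect_equal(f0$subject_variance / (f0$subject_variance + f0$residual_variance),
               0.5, tolerance = 0.12)

  # y = 0.5 x1 + u + e recovered within +/- 0.1 at 50 x 10
  d1 <- simulate_lmm(50, 10, 0.5, sd_u = 0.7, sd_e = 0.7, seed = 15)
  f1 <- random_intercept_lmm(d1, "y", "x1")
  b1 <- unname(f1$betas$beta[f1$betas$term == "x1"])
  sd_y <- 1  # response z-scored; standardized truth:
  truth <- 0.5 * sd(d1$x1) / sd(d1$y)
  expect_lt(abs(b1 - truth), 0.1)
  expect_gt(f1$logLik, as.numeric(stats::logLik(lm(zscore(d1$y) ~ zscore(d1$x1)))))
})

test_that("LMM betas agree with the nlme fitter on the same data", {
  skip_if_not_installed("nlme")
  d <- simulate_lmm(20, 6, 0.4, sd_u = 0.5, sd_e = 0.8, seed = 22)
  fit <- random_intercept_lmm(d, "y", "x1")
  z <- dplyr::mutate(d, y = zscore(y), x1 = zscore(x1))
  ref <- nlme::lme(y ~ x1, random = ~ 1 | subject_id, data = z, method = "ML")
  expect_equal(unname(fit$betas$beta[fit$betas$term == "x1"]),
               unname(nlme::fixef(ref)[["x1"]]), tolerance = 1e-4)
})

test_that("LMM validates grouping and flags collinear designs", {
  d <- simulate_lmm(20, 6, 0.4, 0.5, 0.8, seed = 30)
  d$x2 <- 2 * d$x1
  expect_error(random_intercept_lmm(d, "y", c("x1", "x2")), "collinear.*x2")
  d1 <- d[!duplicated(d$subject_id), ]
  expect_error(random_intercept_lmm(d1, "y", "x1"), "at least 2 observations")
  expect_error(random_intercept_lmm(d, "y", "missing_col"), "missing_col")
})

test_that("tidy and glance methods summarise a fitted gait_lmm", {
  d <- simulate_lmm(15, 5, 0.3, 0.5, 0.8, seed = 40)
  fit <- random_intercept_lmm(d, "y", "x1")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p_value")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 75)
  expect_gte(gl$subject_variance, 0)
})
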