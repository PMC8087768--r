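#' One-tailed Pearson product-moment correlation
#'
#' Sample correlation with the usual t statistic `t = r sqrt(df / (1 - r^2))`
#' on `df = n - 2` degrees of freedom, and the one-tailed p-value in the
#' stated alternative direction. Invariant to positive affine transforms of
#' either variable.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, non-constant.
#' @param direction Alternative hypothesis: `"positive"` or `"negative"`.
#' @return A one-row tibble: `r`, `t_stat`, `df`, `p_one_tailed`, `direction`.
#' @export
pearson_one_tailed <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Correlation is undefined for constant input.")
  r <- cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- if (direction == "positive") pt(t_stat, df, lower.tail = FALSE) else pt(t_stat, df)
  tibble(r = r, t_stat = t_stat, df = df, p_one_tailed = p, direction = direction)
}

#' Centre and scale to z-scores
#'
#' Subtracts the mean and divides by the sample standard deviation, so the
#' output has mean 0 and sample SD 1. Used before mixed-model fitting so
#' coefficients are standardized beta-weights.
#'
#' @param x Numeric vector, `n >= 2`, non-constant.
#' @return The z-scored vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2) abort("Need at least 2 observations to z-score.")
  s <- sd(x)
  if (s == 0) abort("Cannot z-score a constant vector.")
  (x - mean(x)) / s
}

#' Subject-random-intercept linear mixed model with standardized betas
#'
#' Fits `y = X beta + u_subject + e` by maximum likelihood with a single
#' random intercept per subject, after z-scoring the response and every
#' predictor, so the fixed-effect coefficients are standardized beta-weights
#' directly comparable across predictors. Inference on the betas uses Wald
#' z-tests; exact replication of any particular package's denominator
#' degrees of freedom is deliberately out of scope.
#'
#' @param data A data frame of step-level observations.
#' @param response Name of the response column.
#' @param predictors Character vector of fixed-effect column names.
#' @param subject Name of the grouping column. Default `"subject_id"`.
#' @return An object of class `gait_lmm` with `betas` (tibble: `term`,
#'   `beta`, `se`, `statistic`, `p_value`), `subject_variance`,
#'   `residual_variance`, `logLik`, and the underlying `lme4` fit.
#' @export
random_intercept_lmm <- function(data, response, predictors,
                                 subject = "subject_id") {
  cols <- c(response, predictors, subject)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) abort(sprintf("Column '%s' not found in `data`.", miss[1]))
  data <- data[stats::complete.cases(data[, cols]), cols]
  grp <- factor(data[[subject]])
  if (nlevels(grp) < 2 || min(table(grp)) < 2) {
    abort("Need at least 2 subjects with at least 2 observations each.")
  }

  z <- data
  for (v in c(response, predictors)) z[[v]] <- zscore(data[[v]])

  X <- as.matrix(z[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1), qrX$pivot[seq_len(qrX$rank)]) - 1L
    abort(sprintf("Singular fixed-effect design; collinear column(s): %s.",
                  paste(predictors[drop_idx], collapse = ", ")))
  }

  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+ (1 |", subject, ")"))
  fit <- lme4::lmer(fml, data = z, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))

  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  betas <- tibble(
    term = terms,
    beta = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = 2 * stats::pnorm(abs(sm[, "t value"]), lower.tail = FALSE)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      betas = betas,
      subject_variance = vc$vcov[vc$grp == subject][1],
      residual_variance = vc$vcov[vc$grp == "Residual"][1],
      logLik = as.numeric(stats::logLik(fit)),
      n_obs = nrow(z),
      n_subjects = nlevels(grp),
      fit = fit
    ),
    class = "gait_lmm"
  )
}

#' @export
print.gait_lmm <- function(x, ...) {
  cat(sprintf("Subject-random-intercept LMM (ML): %d obs, %d subjects\n",
              x$n_obs, x$n_subjects))
  cat(sprintf("Variance components: subject %.4f, residual %.4f\n",
              x$subject_variance, x$residual_variance))
  print(x$betas)
  invisible(x)
}

#' Tidy a fitted gait mixed model
#'
#' @param x A `gait_lmm` object.
#' @param ... Unused.
#' @return A tibble of standardized fixed-effect estimates with Wald z
#'   statistics and p-values.
#' @export
tidy.gait_lmm <- function(x, ...) {
  rename(x$betas, estimate = "beta", std.error = "se")
}

#' One-line model summary for a gait mixed model
#'
#' @param x A `gait_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble: variance components, log-likelihood, sizes.
#' @export
glance.gait_lmm <- function(x, ...) {
  tibble(
    subject_variance = x$subject_variance,
    residual_variance = x$residual_variance,
    logLik = x$logLik,
    nobs = x$n_obs,
    n_subjects = x$n_subjects
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
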