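#' Plot the ground reaction force of a trial
#'
#' Vertical and fore-aft GRF against time, with the stance phases detected
#' at the configured threshold shaded.
#'
#' @param trial A `gait_trial`.
#' @param threshold Stance threshold (N) for shading.
#' @return A ggplot object.
#' @export
plot_grf <- function(trial, threshold = 20) {
  f <- trial$forces
  stance <- detect_stance(f$fz, trial$force_rate, threshold)
  long <- tidyr::pivot_longer(f[, c("time", "fz", "fx")], c("fz", "fx"),
                              names_to = "component", values_to = "force")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$force,
                                          colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "force (N)",
                  title = sprintf("GRF: subject %s, %s", trial$subject_id, trial$gait)) +
    ggplot2::theme_minimal()
  if (nrow(stance) > 0) {
    shade <- mutate(stance,
                    xmin = f$time[.data$start_frame],
                    xmax = f$time[.data$end_frame - 1L])
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.08)
  }
  p
}

#' Density plot of specific net work by joint and gait
#'
#' Distribution of per-step SNW values for hip, knee and ankle at each
#' gait, with a rug of the individual steps.
#'
#' @param outcomes Outcome tibble from [process_cohort()].
#' @return A ggplot object.
#' @export
plot_snw_density <- function(outcomes) {
  long <- outcomes |>
    filter(.data$snw_defined) |>
    tidyr::pivot_longer(c("snw_hip", "snw_knee", "snw_ankle"),
                        names_to = "joint", values_to = "snw") |>
    mutate(joint = sub("snw_", "", .data$joint))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snw, colour = .data$joint)) +
    ggplot2::geom_density(bounds = c(0, 1)) +
    ggplot2::geom_rug(alpha = 0.3, linewidth = 0.2) +
    ggplot2::facet_wrap(~gait) +
    ggplot2::labs(x = "specific net work", y = "density") +
    ggplot2::theme_minimal()
}

#' Scatter of a tendon outcome against AT moment arm
#'
#' Per-step values of an outcome variable against the subject's static
#' Achilles tendon moment arm, with a least-squares line, faceted by gait.
#'
#' @param outcomes Outcome tibble.
#' @param subjects Subject morphometrics tibble.
#' @param var Outcome column, e.g. `"snw_ankle"`, `"stress_mean_per_kg"`.
#' @param gaits Gaits to include. Default run and sprint.
#' @return A ggplot object.
#' @export
plot_moment_arm_scatter <- function(outcomes, subjects, var = "snw_ankle",
                                    gaits = c("run", "sprint")) {
  dat <- outcomes |>
    filter(.data$snw_defined, .data$gait %in% gaits) |>
    left_join(subjects[, c("subject_id", "at_moment_arm")], by = "subject_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$at_moment_arm * 100,
                                    y = .data[[var]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::facet_wrap(~gait, scales = "free_y") +
    ggplot2::labs(x = "AT moment arm (cm)", y = var) +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort analysis
#'
#' Correlation overview: one-tailed Pearson r against the AT moment arm for
#' each tested variable and gait.
#'
#' @param object A `gait_analysis` from [analyze_outcomes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.gait_analysis <- function(object, ...) {
  d <- mutate(object$correlations,
              significant = .data$p_one_tailed <= 0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gait, y = .data$r,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::labs(y = "one-tailed Pearson r vs AT moment arm") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
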