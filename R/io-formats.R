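#' @title Trial, subject and result file formats
#' @description Tab-delimited UTF-8 text with a one-line header and "."
#'   decimal throughout; SI units on disk (m, N, kg, s), with cm / cm^2
#'   accepted for morphometrics when explicitly declared. Time columns are
#'   authoritative; sampling rates are inferred from them.
#' @name io_formats
NULL

result_columns <- c(
  "subject_id", "gait", "step_index", "froude",
  "snw_hip", "snw_knee", "snw_ankle", "snw_defined",
  "force_impulse", "grf_impulse", "r_ankle_ext",
  "stress_mean", "stress_peak", "strain", "delta_l",
  "energy", "energy_per_kg", "stress_mean_per_kg"
)

# Construct a gait_trial container (validated).
new_gait_trial <- function(subject_id, gait, markers, forces,
                           kinematic_rate, force_rate) {
  trial <- structure(
    list(subject_id = subject_id, gait = gait,
         markers = as_tibble(markers), forces = as_tibble(forces),
         kinematic_rate = kinematic_rate, force_rate = force_rate),
    class = "gait_trial"
  )
  validate_gait_trial(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s, gait %s: %d kinematic frames @ %g Hz, %d force frames @ %g Hz\n",
              x$subject_id, x$gait, nrow(x$markers), x$kinematic_rate,
              nrow(x$forces), x$force_rate))
  invisible(x)
}

check_uniform_time <- function(time, what, tol = 1e-9) {
  if (length(time) < 2) abort(sprintf("%s needs at least 2 frames.", what))
  dt <- diff(time)
  if (any(dt <= 0)) {
    abort(sprintf("%s time column is not monotone increasing at index %d.",
                  what, which(dt <= 0)[1] + 1L))
  }
  bad <- which(abs(dt - dt[1]) > tol)
  if (length(bad) > 0) {
    abort(sprintf("Non-uniform sampling in %s at index %d (step %.9g s vs %.9g s).",
                  what, bad[1] + 1L, dt[bad[1]], dt[1]))
  }
  1 / dt[1]
}

validate_gait_trial <- function(trial) {
  for (m in required_markers) {
    for (ax in c("x", "y")) {
      col <- paste0(m, "_", ax)
      if (!col %in% names(trial$markers)) {
        abort(sprintf("Marker file is missing required column '%s'.", col))
      }
    }
  }
  for (col in c("fz", "fx", "cop_x")) {
    if (!col %in% names(trial$forces)) {
      abort(sprintf("Force file is missing required column '%s'.", col))
    }
  }
  rk <- check_uniform_time(trial$markers$time, "marker series")
  rf <- check_uniform_time(trial$forces$time, "force series")
  if (abs(rk - trial$kinematic_rate) > 1e-6 * rk ||
      abs(rf - trial$force_rate) > 1e-6 * rf) {
    abort("Stated rates disagree with the time columns.")
  }
  ratio <- trial$force_rate / trial$kinematic_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("Force rate must be an integer multiple of the kinematic rate.")
  }
  dur_k <- max(trial$markers$time) - min(trial$markers$time)
  dur_f <- max(trial$forces$time) - min(trial$forces$time)
  if (abs(dur_k - dur_f) > 1 / trial$force_rate + 1e-9) {
    abort("Marker and force series durations differ by more than one force frame.")
  }
  trial
}

#' Read one gait trial from marker and force files
#'
#' Both files are tab-delimited with a one-line header. The marker file has
#' columns `time` and `<name>_x`, `<name>_y` for at least `hip`, `knee`,
#' `ankle`, `mtp`, `heel`; the force file has `time`, `fz`, `fx`, `cop_x`.
#' Time must be monotone with a uniform step (tolerance 1e-9 s), and the
#' force rate an integer multiple of the kinematic rate.
#'
#' @param marker_path,force_path File paths.
#' @param meta Named list with at least `subject_id` and `gait`.
#' @return A validated `gait_trial`.
#' @export
read_trial <- function(marker_path, force_path, meta = list()) {
  markers <- readr::read_tsv(marker_path, show_col_types = FALSE, progress = FALSE)
  forces <- readr::read_tsv(force_path, show_col_types = FALSE, progress = FALSE)
  for (df in list(markers, forces)) {
    if (!"time" %in% names(df)) abort("Missing required column 'time'.")
  }
  rk <- check_uniform_time(markers$time, "marker series")
  rf <- check_uniform_time(forces$time, "force series")
  new_gait_trial(meta$subject_id %||% "unknown", meta$gait %||% "unknown",
                 markers, forces, rk, rf)
}

#' Write one gait trial to marker and force files
#'
#' @param trial A `gait_trial`.
#' @inheritParams read_trial
#' @return The trial, invisibly.
#' @export
write_trial <- function(trial, marker_path, force_path) {
  readr::write_tsv(mutate(trial$markers, across(where(is.numeric), ~signif(.x, 12))),
                   marker_path, progress = FALSE)
  readr::write_tsv(mutate(trial$forces, across(where(is.numeric), ~signif(.x, 12))),
                   force_path, progress = FALSE)
  invisible(trial)
}

validate_subject_row <- function(s) {
  numfields <- c("body_mass", "hip_height", "foot_length", "at_moment_arm",
                 "tendon_csa", "tendon_length")
  for (f in numfields) {
    v <- s[[f]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v) || v <= 0) {
      abort(sprintf("Subject %s: field '%s' must be a positive number.",
                    s$subject_id %||% "?", f))
    }
  }
  if (!s$sex %in% c("M", "F")) {
    abort(sprintf("Subject %s: field 'sex' must be 'M' or 'F'.", s$subject_id))
  }
  if (s$at_moment_arm >= s$foot_length) {
    abort(sprintf("Subject %s: field 'at_moment_arm' must be smaller than foot_length.",
                  s$subject_id))
  }
  if (s$tendon_csa >= 5e-4) {
    abort(sprintf("Subject %s: field 'tendon_csa' exceeds the 5 cm^2 sanity bound.",
                  s$subject_id))
  }
  invisible(s)
}

#' Read a subject configuration file
#'
#' A YAML document with a top-level `subjects:` list, one block per subject
#' with fields `subject_id`, `sex` (M/F), `body_mass` (kg), `hip_height`
#' (m), `foot_length` (m), `at_moment_arm` (m), `tendon_csa` (m^2),
#' `tendon_length` (m). Values in cm / cm^2 are accepted only when declared
#' in a per-subject `units:` map (`at_moment_arm: cm`, `tendon_csa: cm2`,
#' `tendon_length: cm`, ...) and are converted to SI on read. All
#' invariants are checked; a violation raises an error naming the subject
#' and field.
#'
#' @param path Path to the YAML file.
#' @return A tibble of subject morphometrics in SI units.
#' @export
read_subject_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$subjects)) abort("Config must contain a top-level 'subjects:' list.")
  rows <- map(doc$subjects, function(s) {
    units <- s$units %||% list()
    s$units <- NULL
    for (f in names(units)) {
      u <- units[[f]]
      fac <- switch(u, cm = 1e-2, cm2 = 1e-4, m = 1, m2 = 1,
                    abort(sprintf("Subject %s: unknown unit '%s' for field '%s'.",
                                  s$subject_id %||% "?", u, f)))
      s[[f]] <- s[[f]] * fac
    }
    s <- as_tibble(s)
    validate_subject_row(s)
    s
  })
  list_rbind(rows)
}

#' Write a subject configuration file
#'
#' @param subjects A tibble of subject morphometrics (SI units).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_config <- function(subjects, path) {
  blocks <- lapply(seq_len(nrow(subjects)), function(i) {
    as.list(subjects[i, , drop = FALSE])
  })
  yaml::write_yaml(list(subjects = blocks), path, precision = 12)
  invisible(path)
}

#' Write the per-step outcome table
#'
#' Tab-delimited, one row per step, fixed column order (see
#' `gaitspring:::result_columns`). Numeric values are written with 12
#' significant digits so that a write/read round trip preserves them to
#' 1e-10 relative.
#'
#' @param outcomes Outcome tibble from [process_trial()] /
#'   [process_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(outcomes, path) {
  if (is.null(outcomes) || nrow(outcomes) == 0) {
    abort("Refusing to write an empty outcome table.")
  }
  miss <- setdiff(result_columns, names(outcomes))
  if (length(miss) > 0) abort(sprintf("Outcome table is missing column '%s'.", miss[1]))
  out <- outcomes[, result_columns]
  out <- mutate(out, across(where(is.numeric), ~signif(.x, 12)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a per-step outcome table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return The outcome tibble.
#' @export
read_results <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(result_columns, names(out))
  if (length(miss) > 0) abort(sprintf("Result file is missing column '%s'.", miss[1]))
  out
}
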