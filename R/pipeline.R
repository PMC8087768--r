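#' Pipeline configuration
#'
#' Bundles every tunable processing parameter: the zero-lag Butterworth
#' filters (fourth order, 6 Hz for kinematics and 100 Hz for force, the
#' conventional gait-lab settings), whether the COP is filtered with the
#' force filter, the stance detection rule (20 N threshold, 50 ms minimum),
#' the tendon constants, the moment-arm and PCSA models, and the two
#' documented interpretation switches:
#'
#' * `stress_raw_impulse`: report mean stress as raw impulse / CSA (Pa s)
#'   instead of time-averaged force / CSA (Pa).
#' * `eq_arm_numerator`: `"tendon_arm"` (default) weights the external-arm
#'   numerator by the instantaneous tendon moment arm; `"external"` uses
#'   the instantaneous GRF lever `COPx - ankle_x` instead.
#'
#' `filters = FALSE` disables all filtering (used for noise-free oracle
#' comparisons where smoothing would bias the check).
#'
#' @param filter_kinematics,filter_force [filter_spec()]s.
#' @param filter_cop Filter the COP with the force filter? Default `TRUE`.
#' @param filters Master switch; `FALSE` disables all filtering.
#' @param stance_threshold Contact threshold (N).
#' @param stance_min_duration Minimum stance duration (s).
#' @param tendon A [tendon_constants()].
#' @param moment_arms A [moment_arm_model()].
#' @param pcsa A [pcsa_partition()].
#' @param inertia A [segment_inertia()] table.
#' @param stress_raw_impulse,eq_arm_numerator See Details.
#' @param g Gravitational acceleration (m/s^2).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter_kinematics = filter_spec(4, 6),
                            filter_force = filter_spec(4, 100),
                            filter_cop = TRUE,
                            filters = TRUE,
                            stance_threshold = 20,
                            stance_min_duration = 0.05,
                            tendon = tendon_constants(),
                            moment_arms = moment_arm_model(),
                            pcsa = pcsa_partition(),
                            inertia = segment_inertia(),
                            stress_raw_impulse = FALSE,
                            eq_arm_numerator = c("tendon_arm", "external"),
                            g = GRAVITY) {
  structure(
    list(filter_kinematics = filter_kinematics, filter_force = filter_force,
         filter_cop = isTRUE(filter_cop), filters = isTRUE(filters),
         stance_threshold = stance_threshold,
         stance_min_duration = stance_min_duration,
         tendon = tendon, moment_arms = moment_arms, pcsa = pcsa,
         inertia = inertia, stress_raw_impulse = isTRUE(stress_raw_impulse),
         eq_arm_numerator = match.arg(eq_arm_numerator), g = g),
    class = "pipeline_config"
  )
}

#' Process one gait trial into per-step tendon outcomes
#'
#' The full inverse-dynamics pipeline: filter the marker and force series,
#' downsample force to the kinematic rate (phase aligned), detect support
#' phases, compute joint angles, net joint moments by the free-body
#' recursion, muscle forces with bi-articular corrections, the joint work
#' decomposition, and assemble one tendon outcome row per detected step.
#'
#' @param trial A `gait_trial` (from [read_trial()] or [generate_trial()]).
#' @param subject The matching one-row subject morphometrics table.
#' @param config A [pipeline_config()].
#' @param keep_kinetics If `TRUE`, attach the per-step kinetic time series
#'   (moments, forces, powers) as the `"kinetics"` attribute.
#' @return A tibble of per-step outcomes (possibly zero rows if no stance
#'   was detected).
#' @export
process_trial <- function(trial, subject, config = pipeline_config(),
                          keep_kinetics = FALSE) {
  rate_k <- trial$kinematic_rate
  rate_f <- trial$force_rate

  mk <- trial$markers
  if (config$filters) {
    for (cn in setdiff(names(mk), "time")) {
      mk[[cn]] <- zero_lag_butterworth(mk[[cn]], rate_k, config$filter_kinematics)
    }
  }
  fz <- trial$forces$fz
  fx <- trial$forces$fx
  cop <- trial$forces$cop_x
  if (config$filters) {
    fz <- zero_lag_butterworth(fz, rate_f, config$filter_force)
    fx <- zero_lag_butterworth(fx, rate_f, config$filter_force)
    if (config$filter_cop) cop <- zero_lag_butterworth(cop, rate_f, config$filter_force)
  }
  fz_k <- downsample_force(fz, rate_f, rate_k, antialias = NULL)[seq_len(nrow(mk))]
  fx_k <- downsample_force(fx, rate_f, rate_k, antialias = NULL)[seq_len(nrow(mk))]
  cop_k <- downsample_force(cop, rate_f, rate_k, antialias = NULL)[seq_len(nrow(mk))]

  steps <- detect_stance(fz_k, rate_k, config$stance_threshold,
                         config$stance_min_duration)
  if (nrow(steps) == 0) return(empty_outcomes())

  step_df <- bind_cols(mk, tibble(fz = fz_k, fx = fx_k, cop_x = cop_k))
  angles <- joint_angles(mk)
  omega <- tibble(
    hip = finite_diff_velocity(angles$hip * pi / 180, rate_k),
    knee = finite_diff_velocity(angles$knee * pi / 180, rate_k),
    ankle = finite_diff_velocity(angles$ankle * pi / 180, rate_k)
  )
  moments <- net_joint_moments(step_df, subject$body_mass, rate_k,
                               inertia = config$inertia, g = config$g)
  scales <- subject_arm_scales(subject, config$moment_arms)

  kinetics <- list()
  rows <- map(seq_len(nrow(steps)), function(i) {
    w <- steps[i, ]
    idx <- window_frames(w, nrow(mk))
    mom_w <- moments[idx, ]
    ang_w <- angles[idx, ]
    mf <- muscle_forces(mom_w, ang_w, config$moment_arms, config$pcsa, scales)

    work <- imap(c(hip = "hip", knee = "knee", ankle = "ankle"), function(j, nm) {
      joint_power_work(mom_w[[j]], omega[[j]][idx], rate_k)
    })
    grf_mag <- sqrt(fz_k[idx]^2 + fx_k[idx]^2)
    arm_num <- switch(config$eq_arm_numerator,
                      tendon_arm = mf$r_ankle,
                      external = cop_k[idx] - mk$ankle_x[idx])
    r_ext <- external_moment_arm_ankle(grf_mag, arm_num, mf$ankle, rate_k)
    dur <- w$duration
    hipx <- mk$hip_x[idx]
    speed <- (hipx[length(hipx)] - hipx[1]) / dur
    kin <- tibble(
      gait = trial$gait, step_index = i,
      work_pos_hip = work$hip$work_pos, work_neg_hip = work$hip$work_neg,
      work_pos_knee = work$knee$work_pos, work_neg_knee = work$knee$work_neg,
      work_pos_ankle = work$ankle$work_pos, work_neg_ankle = work$ankle$work_neg,
      force_impulse = trapz_integral(mf$ankle, rate_k),
      peak_force = max(mf$ankle),
      grf_impulse = trapz_integral(grf_mag, rate_k),
      r_ankle_ext = r_ext,
      stance_duration = dur,
      froude = froude_number(max(speed, 1e-6), subject$hip_height, config$g)
    )
    if (keep_kinetics) {
      kinetics[[i]] <<- bind_cols(
        tibble(time = mk$time[idx]), mom_w[, c("ankle", "knee", "hip")] |>
          rename_with(~paste0("moment_", .x)),
        mf[, c("ankle", "knee", "hip", "r_ankle")] |>
          rename_with(~paste0("force_", .x), c("ankle", "knee", "hip")),
        tibble(power_ankle = work$ankle$power, power_knee = work$knee$power,
               power_hip = work$hip$power)
      )
    }
    assemble_outcomes(kin, subject, config$tendon,
                      raw_impulse = config$stress_raw_impulse)
  })
  out <- list_rbind(rows)
  if (keep_kinetics) attr(out, "kinetics") <- kinetics
  out
}

empty_outcomes <- function() {
  out <- as_tibble(setNames(rep(list(numeric(0)), length(result_columns)),
                            result_columns))
  out$subject_id <- character(0)
  out$gait <- character(0)
  out$snw_defined <- logical(0)
  out
}

#' Process a cohort of trials
#'
#' @param cohort A list as returned by [generate_cohort()], or a list with
#'   elements `trials` (list of `gait_trial`) and `subjects` (tibble).
#' @param config A [pipeline_config()].
#' @return The combined per-step outcome tibble.
#' @export
process_cohort <- function(cohort, config = pipeline_config()) {
  subjects <- cohort$subjects
  rows <- map(cohort$trials, function(tr) {
    subj <- subjects[subjects$subject_id == tr$subject_id, ]
    if (nrow(subj) != 1) abort(sprintf("No morphometrics for subject '%s'.", tr$subject_id))
    process_trial(tr, subj, config)
  })
  out <- list_rbind(rows)
  # step_index enumerates steps within subject x gait across trials
  out |>
    group_by(.data$subject_id, .data$gait) |>
    mutate(step_index = row_number()) |>
    ungroup()
}

#' Cohort-level statistical analysis of tendon outcomes
#'
#' Reproduces the standard analysis stage on an outcome table:
#'
#' 1. per-gait summary (mean and SD of Froude number and SNW per joint);
#' 2. one-tailed Pearson correlations of ankle SNW (alternative: positive),
#'    mass-specific mean tendon stress and mass-specific elastic energy
#'    (alternative: negative) against the subject's static AT moment arm.
#'    SNW is tested at every gait; the tendon-loading variables at run and
#'    sprint, where elastic loading is the hypothesis of interest;
#' 3. optionally, a subject-random-intercept mixed model of ankle SNW at
#'    sprint with z-scored fixed effects: AT moment arm, external moment
#'    arm, body mass, Froude number, GRF impulse and tendon CSA.
#'
#' Correlations are computed at step level by default (each step one
#' observation); `by = "subject"` correlates subject means instead.
#'
#' @param outcomes Outcome tibble from [process_cohort()].
#' @param subjects Subject morphometrics tibble.
#' @param lmm_gait Gait for the mixed model, or `NULL` to skip. Default
#'   `"sprint"`.
#' @param by `"step"` (default) or `"subject"`.
#' @return A `gait_analysis` list: `gait_summary`, `correlations`, `lmm`.
#' @export
analyze_outcomes <- function(outcomes, subjects, lmm_gait = "sprint",
                             by = c("step", "subject")) {
  by <- match.arg(by)
  dat <- outcomes |>
    filter(.data$snw_defined) |>
    left_join(subjects[, c("subject_id", "body_mass", "at_moment_arm",
                           "tendon_csa")], by = "subject_id")

  gait_summary <- outcomes |>
    group_by(.data$gait) |>
    summarise(across(c("froude", "snw_hip", "snw_knee", "snw_ankle"),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              n_steps = dplyr::n(), .groups = "drop")

  cor_one <- function(d, var, direction, gait) {
    d <- d[d$gait == gait, ]
    if (by == "subject") {
      d <- d |>
        group_by(.data$subject_id) |>
        summarise(at_moment_arm = first(.data$at_moment_arm),
                  value = mean(.data[[var]]), .groups = "drop")
    } else {
      d$value <- d[[var]]
    }
    if (nrow(d) < 3 || sd(d$value) == 0) return(NULL)
    res <- pearson_one_tailed(d$at_moment_arm, d$value, direction)
    bind_cols(tibble(variable = var, gait = gait), res)
  }
  cors <- list()
  for (g in unique(dat$gait)) cors <- c(cors, list(cor_one(dat, "snw_ankle", "positive", g)))
  for (g in intersect(c("run", "sprint"), unique(dat$gait))) {
    cors <- c(cors, list(cor_one(dat, "stress_mean_per_kg", "negative", g)))
    cors <- c(cors, list(cor_one(dat, "energy_per_kg", "negative", g)))
  }
  correlations <- list_rbind(purrr::compact(cors))

  lmm <- NULL
  if (!is.null(lmm_gait) && lmm_gait %in% dat$gait) {
    d <- dat[dat$gait == lmm_gait, ]
    enough <- nrow(d) >= 12 && length(unique(d$subject_id)) >= 2 &&
      min(table(d$subject_id)) >= 2
    if (enough) {
      lmm <- tryCatch(
        random_intercept_lmm(
          d, "snw_ankle",
          c("at_moment_arm", "r_ankle_ext", "body_mass", "froude",
            "grf_impulse", "tendon_csa")),
        error = function(e) NULL)
    }
  }
  structure(list(gait_summary = gait_summary, correlations = correlations,
                 lmm = lmm),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Per-gait summary (mean/SD):\n")
  print(x$gait_summary)
  cat("\nOne-tailed Pearson correlations vs AT moment arm:\n")
  print(x$correlations)
  if (!is.null(x$lmm)) {
    cat("\nMixed model of ankle SNW (standardized betas):\n")
    print(x$lmm)
  }
  invisible(x)
}

#' Write a plain-text analysis report
#'
#' @param analysis A `gait_analysis` from [analyze_outcomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(analysis, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  sink(con)
  print(analysis)
  sink()
  invisible(path)
}
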