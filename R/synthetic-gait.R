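#' Specify a synthetic cohort
#'
#' Describes a cohort of synthetic subjects and the gait trials to generate
#' for them. Defaults emulate a recreationally fit adult cohort of 24
#' subjects walking to sprinting barefoot over floor-mounted force plates:
#' body mass 64.15 +/- 9.84 kg, Achilles tendon (AT) moment arm
#' 4.27 +/- 0.48 cm spanning roughly 3.1-5.0 cm and positively correlated
#' with mass (target r ~ 0.62).
#'
#' `effect_injection = TRUE` (default) generates trials in which the ankle
#' muscle force follows `F = M / r`, so subjects with shorter AT moment arms
#' carry proportionally larger tendon loads, and short-heeled subjects push
#' off less steeply at run/sprint (more spring-like ankle behaviour). With
#' `effect_injection = FALSE` the COP lever is rescaled with each subject's
#' moment arm so joint moments are proportional to `r` and tendon loading is
#' independent of heel length, and the moment arm is drawn independently of
#' every other trait (no allometric path can imitate the effect) - a null
#' cohort.
#'
#' @param n_subjects Number of subjects (>= 2). Default 24.
#' @param steps_per_gait Trials (one stance each) per subject per gait.
#' @param gaits Character vector from `walk`, `fast_walk`, `jog`, `run`,
#'   `sprint`.
#' @param seed Master seed; the same seed reproduces the cohort bit for bit.
#' @param at_moment_arm_range AT moment arm truncation range (m).
#' @param mass_range Body mass truncation range (kg).
#' @param effect_injection Logical, see Details.
#' @param noise_marker_sd Marker noise SD (m), default 1 mm; 0 disables.
#' @param noise_force_sd Force noise SD (N), default 2 N; 0 disables.
#' @param kinematic_rate,force_rate Sampling rates (Hz).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 24, steps_per_gait = 3,
                        gaits = c("walk", "fast_walk", "jog", "run", "sprint"),
                        seed = 1,
                        at_moment_arm_range = c(0.0312, 0.0501),
                        mass_range = c(40, 90),
                        effect_injection = TRUE,
                        noise_marker_sd = 0.001,
                        noise_force_sd = 2,
                        kinematic_rate = 500,
                        force_rate = 1000) {
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  gaits <- match.arg(gaits, several.ok = TRUE)
  for (rg in list(at_moment_arm_range, mass_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) abort("Ranges must be ordered c(low, high) with low <= high.")
  }
  k <- force_rate / kinematic_rate
  if (abs(k - round(k)) > 1e-9) abort("`force_rate` must be an integer multiple of `kinematic_rate`.")
  structure(
    list(n_subjects = as.integer(n_subjects),
         steps_per_gait = as.integer(steps_per_gait), gaits = gaits,
         seed = as.integer(seed), at_moment_arm_range = at_moment_arm_range,
         mass_range = mass_range, effect_injection = isTRUE(effect_injection),
         noise_marker_sd = noise_marker_sd, noise_force_sd = noise_force_sd,
         kinematic_rate = kinematic_rate, force_rate = force_rate),
    class = "cohort_spec"
  )
}

# Per-gait generator parameters. Froude means/SDs follow typical
# self-selected overground speeds from walking to sprinting; stance
# durations, GRF peak multiples of body weight, fore-aft amplitudes and
# push-off pitch are standard stance morphology per gait.
gait_params <- function(gait = NULL) {
  tbl <- tibble(
    gait = c("walk", "fast_walk", "jog", "run", "sprint"),
    froude_mean = c(0.130, 0.245, 0.362, 0.662, 1.086),
    froude_sd = c(0.041, 0.054, 0.086, 0.179, 0.283),
    stance_s = c(0.65, 0.50, 0.32, 0.26, 0.19),
    double_peak = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    peak_bw = c(1.12, 1.28, 2.30, 2.50, 2.72),
    peak_lo = c(1.00, 1.10, 2.20, 2.30, 2.40),
    peak_hi = c(1.25, 1.45, 2.50, 2.70, 2.80),
    fx_amp = c(0.18, 0.25, 0.35, 0.40, 0.45),
    pushoff_deg = c(34, 31, 18, 30, 46),
    bounce = c(0.015, 0.018, -0.045, -0.050, -0.060)
  )
  if (is.null(gait)) return(tbl)
  row <- tbl[tbl$gait == gait, ]
  if (nrow(row) == 0) abort(sprintf("Unsupported gait label '%s'.", gait))
  row
}

#' Generate one synthetic subject
#'
#' Draws morphometrics from truncated normal distributions matching the
#' cohort defaults (mass 64.15 +/- 9.84 kg; AT moment arm 4.27 +/- 0.48 cm,
#' positively correlated with mass, target r ~ 0.62) unless overridden by
#' the spec ranges. Secondary morphometrics (hip height, foot length,
#' tendon CSA and resting length) scale allometrically with body size, so a
#' degenerate spec (collapsed ranges) yields identical subjects.
#'
#' @param spec A [cohort_spec()].
#' @param index Subject index, `1..n_subjects`.
#' @return A one-row tibble of subject morphometrics.
#' @export
generate_subject <- function(spec, index) {
  if (index < 1 || index > spec$n_subjects) abort("`index` out of range for this spec.")
  with_seed(child_seed(spec$seed, 1L, index), {
    mass <- rtruncnorm1(1, 64.15, 9.84, spec$mass_range[1], spec$mass_range[2])
    z_mass <- (mass - 64.15) / 9.84
    if (spec$effect_injection) {
      # moment arm conditionally normal given mass; the loading on the
      # shared mass factor is inflated slightly above the target
      # correlation to offset attenuation from range truncation
      arm <- rtruncnorm1(1, 0.0427 + 0.68 * 0.0048 * z_mass,
                         0.0048 * sqrt(1 - 0.68^2),
                         spec$at_moment_arm_range[1], spec$at_moment_arm_range[2])
      # CSA scales allometrically with mass with a mild heel-length factor
      # (keeps it from being an exact linear function of mass)
      csa <- 0.61e-4 * (mass / 64.15)^0.7 * (arm / 0.0427)^0.4
    } else {
      # null cohort: heel length fully decoupled from every other trait so
      # no allometric path can imitate an r-mediated loading effect
      arm <- rtruncnorm1(1, 0.0427, 0.0048,
                         spec$at_moment_arm_range[1], spec$at_moment_arm_range[2])
      csa <- 0.61e-4 * (mass / 64.15)
    }
    hip_height <- 0.80 + 0.0012 * mass
    tibble(
      subject_id = sprintf("S%03d", index),
      sex = if ((index - 1) %% 24 < 7) "M" else "F",
      body_mass = mass,
      hip_height = hip_height,
      foot_length = 0.28 * hip_height,
      at_moment_arm = arm,
      tendon_csa = csa,
      tendon_length = 0.215 * hip_height
    )
  })
}

#' Generate a stance-phase ground reaction force waveform
#'
#' Vertical GRF is built from raised-cosine lobes: two overlapping lobes
#' (double peak, ~1.1 x body weight each) for walking gaits, one lobe
#' (single peak, ~2.2-2.8 x body weight) for running gaits, windowed so the
#' force is zero at both ends of stance and non-negative throughout.
#' Fore-aft force is a braking-then-propulsive sinusoid with (analytically)
#' zero net impulse, and the centre of pressure travels monotonically from
#' heel to toe.
#'
#' @param gait Gait label.
#' @param mass Body mass (kg).
#' @param duration Stance duration (s), in `[0.08, 1.2]`.
#' @param rate Sampling rate (Hz), `>= 200`.
#' @param seed Seed for the peak-amplitude jitter; `NULL` for no jitter.
#' @param foot_length Foot length (m) for the COP excursion.
#' @return A tibble `time`, `fz`, `fx`, `cop_rel` (COP relative to the heel
#'   contact point, m), sampled at `rate` over `[0, duration]`.
#' @export
generate_stance_grf <- function(gait, mass, duration, rate, seed = NULL,
                                foot_length = 0.25) {
  p <- gait_params(gait)
  if (duration < 0.08 || duration > 1.2) abort("`duration` must lie in [0.08, 1.2] s.")
  if (rate < 200) abort("`rate` must be at least 200 Hz.")
  jitter <- if (is.null(seed)) 0 else with_seed(seed, rnorm(1, 0, 0.03))
  peak <- min(max(p$peak_bw * (1 + jitter), p$peak_lo), p$peak_hi)

  t <- seq(0, duration, by = 1 / rate)
  u <- t / duration
  env <- sin(pi * pmin(pmax(u, 0), 1))^0.25
  bw <- mass * GRAVITY

  lobe <- function(c0, w) {
    z <- (u - c0) / w
    ifelse(abs(z) < 0.5, cos(pi * z)^2, 0)
  }
  fz <- if (p$double_peak) {
    peak * bw * (lobe(0.30, 0.70) + lobe(0.70, 0.70)) * env
  } else {
    peak * bw * lobe(0.50, 1.00) * env
  }
  fz[u <= 0 | u >= 1] <- 0   # exact touchdown / toe-off zeros
  fx <- -p$fx_amp * bw * sin(2 * pi * u)
  cop_rel <- 0.02 + (foot_length - 0.05) * smoothstep(u)
  tibble(time = t, fz = fz, fx = fx, cop_rel = cop_rel)
}

# ---------------------------------------------------------------------------
# Trial construction

# Analytic stance kinematics: time functions valid over the whole trial
# (stance plus swing padding), parameterised by stance progress
# u = (t - t_contact) / T_stance. Returns marker positions at the requested
# times. All shapes are C1-smooth so finite differences are well behaved.
trial_kinematics <- function(t, t1, T_s, subject, gait_row, v, pushoff_rad,
                             hip_drop) {
  fl <- subject$foot_length
  h <- subject$hip_height
  Lt <- 0.50 * h
  Ls <- 0.46 * h
  u <- (t - t1) / T_s

  # foot: metatarsal head anchored; heel rises about it at push-off
  x_mtp <- 0.90 * fl
  phi_f <- -pushoff_rad * smoothstep((u - 0.60) / 0.40)
  heel_x <- x_mtp - 0.90 * fl * cos(phi_f)
  heel_y <- 0.02 - 0.90 * fl * sin(phi_f)
  ux <- cos(phi_f); uy <- sin(phi_f)
  nx <- -sin(phi_f); ny <- cos(phi_f)
  ankle_x <- heel_x + 0.24 * fl * ux + 0.08 * nx
  ankle_y <- heel_y + 0.24 * fl * uy + 0.08 * ny

  # hip: steady progression with a small in-stance oscillation; vertical
  # bounce upward mid-stance for walking (inverted pendulum), downward for
  # running (compliant leg)
  t_mid <- t1 + T_s / 2
  hip_x <- 0.24 * fl + v * (t - t_mid) + 0.008 * sin(2 * pi * u)
  H0 <- 0.955 * h - hip_drop
  hip_y <- H0 + gait_row$bounce * sin(pi * u)^2

  # knee by two-link inverse kinematics, knee-forward branch
  dx <- hip_x - ankle_x
  dy <- hip_y - ankle_y
  D <- sqrt(dx^2 + dy^2)
  D <- pmin(D, 0.995 * (Lt + Ls))
  gamma <- atan2(dy, dx)
  cos_a <- pmin(pmax((Ls^2 + D^2 - Lt^2) / (2 * Ls * D), -1), 1)
  a <- acos(cos_a)
  knee_x <- ankle_x + Ls * cos(gamma - a)
  knee_y <- ankle_y + Ls * sin(gamma - a)

  tibble(time = t,
         hip_x = hip_x, hip_y = hip_y,
         knee_x = knee_x, knee_y = knee_y,
         ankle_x = ankle_x, ankle_y = ankle_y,
         mtp_x = rep(x_mtp, length(t)), mtp_y = rep(0.02, length(t)),
         heel_x = heel_x, heel_y = heel_y)
}

# Forward ground-truth kinetics: an independent transcription of the planar
# Newton-Euler free-body equations, kept separate from the inverse-dynamics
# module so the two can cross-check each other.
truth_free_body <- function(markers, fz, fx, cop_x, rate, body_mass,
                            inertia = segment_inertia(), g = GRAVITY) {
  col <- function(nm) markers[[nm]]
  p_of <- function(s) inertia[inertia$segment == s, ]

  one_segment <- function(px, py, dx_, dy_, s) {
    pr <- p_of(s)
    cx <- px + pr$com_frac * (dx_ - px)
    cy <- py + pr$com_frac * (dy_ - py)
    L <- mean(sqrt((dx_ - px)^2 + (dy_ - py)^2))
    phi <- unwrap_angle(atan2(dy_ - py, dx_ - px))
    m <- pr$mass_frac * body_mass
    list(m = m, I = m * (pr$gyration_frac * L)^2, cx = cx, cy = cy,
         ax = finite_diff_accel(cx, rate), ay = finite_diff_accel(cy, rate),
         alpha = finite_diff_accel(phi, rate))
  }
  foot <- one_segment(col("heel_x"), col("heel_y"), col("mtp_x"), col("mtp_y"), "foot")
  shank <- one_segment(col("knee_x"), col("knee_y"), col("ankle_x"), col("ankle_y"), "shank")
  thigh <- one_segment(col("hip_x"), col("hip_y"), col("knee_x"), col("knee_y"), "thigh")

  xp <- function(rx, ry, Fx, Fy) rx * Fy - ry * Fx

  Rax <- foot$m * foot$ax - fx
  Ray <- foot$m * foot$ay - fz + foot$m * g
  Ma <- foot$I * foot$alpha -
    xp(cop_x - foot$cx, -foot$cy, fx, fz) -
    xp(col("ankle_x") - foot$cx, col("ankle_y") - foot$cy, Rax, Ray)

  Rkx <- shank$m * shank$ax + Rax
  Rky <- shank$m * shank$ay + Ray + shank$m * g
  Mk <- shank$I * shank$alpha + Ma -
    xp(col("ankle_x") - shank$cx, col("ankle_y") - shank$cy, -Rax, -Ray) -
    xp(col("knee_x") - shank$cx, col("knee_y") - shank$cy, Rkx, Rky)

  Rhx <- thigh$m * thigh$ax + Rkx
  Rhy <- thigh$m * thigh$ay + Rky + thigh$m * g
  Mh <- thigh$I * thigh$alpha + Mk -
    xp(col("knee_x") - thigh$cx, col("knee_y") - thigh$cy, -Rkx, -Rky) -
    xp(col("hip_x") - thigh$cx, col("hip_y") - thigh$cy, Rhx, Rhy)

  tibble(time = markers$time, ankle = -Ma, knee = Mk, hip = -Mh)
}

#' Generate one synthetic gait trial with forward ground truth
#'
#' Prescribes smooth stance kinematics (metatarsal-anchored foot with a
#' push-off heel rise, constant-speed hip with gait-appropriate vertical
#' bounce, knee by two-link inverse kinematics), evaluates the stance GRF
#' waveform on the force-plate grid, embeds the stance in swing padding,
#' and computes ground-truth net joint moments, ankle muscle force and
#' stored tendon energy by the forward free-body construction on the
#' noise-free series. Measurement noise (marker and force) is then added to
#' the recorded trial, never to the truth channel.
#'
#' @param subject One row from [generate_subject()].
#' @param gait Gait label.
#' @param spec A [cohort_spec()].
#' @param seed Trial seed (integer). Derive with the spec seed for
#'   cohort-level reproducibility.
#' @return A list with `trial` (a `gait_trial`) and `truth` (a `gait_truth`:
#'   per-frame `moments`, `f_ankle`, the true stance interval on the
#'   kinematic grid, and scalar `energy`).
#' @export
generate_trial <- function(subject, gait, spec, seed) {
  p <- gait_params(gait)
  rate_k <- spec$kinematic_rate
  rate_f <- spec$force_rate

  par <- with_seed(child_seed(seed, 2L), {
    list(
      # Froude target jittered with the per-gait SD, truncated to +/- 1.2 SD
      # so draws stay gait-typical and gaits do not overlap
      froude = rtruncnorm1(1, p$froude_mean, p$froude_sd,
                           max(p$froude_mean - 1.2 * p$froude_sd, 0.02),
                           p$froude_mean + 1.2 * p$froude_sd),
      T_s = p$stance_s * (1 + 0.05 * rnorm(1)),
      push_noise = 1 + 0.25 * rnorm(1),
      hip_drop = abs(rnorm(1, 0, 0.004))
    )
  })
  T_s <- round(par$T_s * rate_k) / rate_k
  t1 <- round(0.15 * rate_k) / rate_k
  T_tot <- t1 + T_s + 0.15
  n_k <- round(T_tot * rate_k) + 1
  t_k <- (seq_len(n_k) - 1) / rate_k
  t_f <- (seq_len((n_k - 1) * round(rate_f / rate_k) + 1) - 1) / rate_f

  v <- sqrt(par$froude * GRAVITY * subject$hip_height)

  # push-off pitch: the effect-injection channel for spring-like behaviour
  z_r <- min(max((subject$at_moment_arm - 0.0427) / 0.0048, -2), 2)
  inject <- spec$effect_injection && gait %in% c("run", "sprint")
  push_deg <- p$pushoff_deg * par$push_noise * (1 + if (inject) 0.25 * z_r else 0)
  push_deg <- min(max(push_deg, 8), 55)

  markers_nf <- trial_kinematics(t_k, t1, T_s, subject, p, v,
                                 push_deg * pi / 180, par$hip_drop)

  # stance GRF on the force grid; COP held at its stance end values outside
  # stance so filtering sees no step discontinuity
  grf <- generate_stance_grf(gait, subject$body_mass, T_s, rate_f,
                             seed = child_seed(seed, 3L),
                             foot_length = subject$foot_length)
  lever_scale <- if (spec$effect_injection) 1 else subject$at_moment_arm / 0.0427
  ankle_ground_x <- 0.24 * subject$foot_length
  place_force <- function(tt) {
    uu <- (tt - t1) / T_s
    inside <- uu >= 0 & uu <= 1
    fz <- numeric(length(tt)); fxv <- numeric(length(tt))
    fz[inside] <- approx(grf$time, grf$fz, xout = tt[inside] - t1)$y
    fxv[inside] <- approx(grf$time, grf$fx, xout = tt[inside] - t1)$y
    cop_rel <- approx(grf$time, grf$cop_rel, xout = pmin(pmax(tt - t1, 0), T_s))$y
    cop <- ankle_ground_x + lever_scale * (cop_rel - 0.24 * subject$foot_length)
    tibble(time = tt, fz = fz, fx = fxv, cop_x = cop)
  }
  force_f <- place_force(t_f)
  force_k <- place_force(t_k)  # analytic evaluation == exact decimation

  # ---- forward ground truth on the noise-free series --------------------
  truth_m <- truth_free_body(markers_nf, force_k$fz, force_k$fx, force_k$cop_x,
                             rate_k, subject$body_mass)
  phi_shank <- unwrap_angle(atan2(markers_nf$knee_y - markers_nf$ankle_y,
                                  markers_nf$knee_x - markers_nf$ankle_x))
  phi_foot <- unwrap_angle(atan2(markers_nf$mtp_y - markers_nf$heel_y,
                                 markers_nf$mtp_x - markers_nf$heel_x))
  theta_ankle <- (phi_shank - phi_foot) * 180 / pi
  arm_scale <- subject$at_moment_arm / moment_arm(moment_arm_model(), "ankle", 90)
  r_ankle <- moment_arm(moment_arm_model(), "ankle", theta_ankle, arm_scale)
  f_ankle <- truth_m$ankle / r_ankle

  stance <- detect_stance(force_k$fz, rate_k)
  energy <- NA_real_
  if (nrow(stance) >= 1) {
    w <- stance[1, ]
    dur <- w$duration
    f_mean <- max(trapz_integral(f_ankle, rate_k, w) / dur, 0)
    stress <- f_mean / subject$tendon_csa
    dl <- stress / 819e6 * subject$tendon_length
    energy <- 0.5 * f_mean * dl * 0.93
  }

  # ---- recorded trial: add measurement noise ----------------------------
  noisy <- with_seed(child_seed(seed, 4L), {
    mk <- markers_nf
    if (spec$noise_marker_sd > 0) {
      for (cn in setdiff(names(mk), "time")) {
        mk[[cn]] <- mk[[cn]] + rnorm(nrow(mk), 0, spec$noise_marker_sd)
      }
    }
    ff <- force_f
    if (spec$noise_force_sd > 0) {
      ff$fz <- pmax(ff$fz + rnorm(nrow(ff), 0, spec$noise_force_sd), 0)
      ff$fx <- ff$fx + rnorm(nrow(ff), 0, spec$noise_force_sd)
    }
    list(markers = mk, forces = ff)
  })

  trial <- new_gait_trial(subject$subject_id, gait, noisy$markers, noisy$forces,
                          rate_k, rate_f)
  truth <- structure(
    list(moments = truth_m, f_ankle = f_ankle, stance = stance,
         energy = energy, markers = markers_nf, force_k = force_k,
         pushoff_deg = push_deg),
    class = "gait_truth"
  )
  list(trial = trial, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Subjects, trials (one stance per trial: `n_subjects * length(gaits) *
#' steps_per_gait` in total) and their ground truths. Child seeds are
#' derived per subject and trial from the master seed, so regeneration is
#' bit-identical and independent of order.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `subjects` tibble, `trials` list of `gait_trial`,
#'   `truths` list of `gait_truth`, and an `index` tibble mapping
#'   `subject_id`, `gait`, `step_index` to positions in those lists.
#' @export
generate_cohort <- function(spec) {
  subjects <- list_rbind(map(seq_len(spec$n_subjects), ~generate_subject(spec, .x)))
  trials <- list()
  truths <- list()
  idx <- list()
  pos <- 0L
  for (i in seq_len(spec$n_subjects)) {
    subj <- subjects[i, ]
    for (gi in seq_along(spec$gaits)) {
      for (si in seq_len(spec$steps_per_gait)) {
        pos <- pos + 1L
        out <- generate_trial(subj, spec$gaits[gi], spec,
                              seed = child_seed(spec$seed, 2L, i, gi, si))
        trials[[pos]] <- out$trial
        truths[[pos]] <- out$truth
        idx[[pos]] <- tibble(subject_id = subj$subject_id,
                             gait = spec$gaits[gi], step_index = si,
                             trial = pos)
      }
    }
  }
  list(subjects = subjects, trials = trials, truths = truths,
       index = list_rbind(idx))
}
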