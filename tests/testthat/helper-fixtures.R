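# Shared fixtures: tiny noise-free cohorts and a static-posture trial
# builder used by the inverse-dynamics oracles.

noise_free_spec <- function(n_subjects = 3, gaits = c("walk", "run"),
                            steps_per_gait = 1, seed = 101) {
  cohort_spec(n_subjects = n_subjects, steps_per_gait = steps_per_gait,
              gaits = gaits, seed = seed,
              noise_marker_sd = 0, noise_force_sd = 0)
}

# A static standing posture held for `n` frames with the GRF equal to body
# weight applied through a fixed COP. Limb geometry: vertical shank and
# thigh over a flat foot.
static_step <- function(n = 50, mass = 70, cop_x = 0.12, rate = 500,
                        ankle_x = 0.06) {
  t <- (seq_len(n) - 1) / rate
  tibble::tibble(
    time = t,
    hip_x = ankle_x, hip_y = 0.90,
    knee_x = ankle_x, knee_y = 0.48,
    ankle_x = ankle_x, ankle_y = 0.08,
    mtp_x = 0.20, mtp_y = 0.02,
    heel_x = 0.0, heel_y = 0.02,
    fz = mass * 9.81, fx = 0, cop_x = cop_x
  )
}

# Inertia table with massless segments: isolates the GRF lever terms so
# static checks have closed forms.
massless_inertia <- function() {
  segment_inertia(
    foot  = c(mass_frac = 0, com_frac = 0.50,  gyration_frac = 0.475),
    shank = c(mass_frac = 0, com_frac = 0.433, gyration_frac = 0.302),
    thigh = c(mass_frac = 0, com_frac = 0.433, gyration_frac = 0.323)
  )
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected))
  expect_lt(max(abs(actual - expected)) / max(scale, .Machine$double.eps), tol)
}
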