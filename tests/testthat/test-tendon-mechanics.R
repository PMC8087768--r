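test_that("SNW hits its spring and motor limits and stays in [0, 1]", {
  expect_equal(specific_net_work(5, -5), 0)   # perfect spring
  expect_equal(specific_net_work(5, 0), 1)    # pure motor
  expect_equal(specific_net_work(0, -4), 1)   # pure brake
  expect_equal(specific_net_work(3, -1), 0.5)

  set.seed(3)
  wp <- abs(rnorm(1e4)); wn <- -abs(rnorm(1e4))
  keep <- wp + abs(wn) > 0
  s <- specific_net_work(wp[keep], wn[keep])
  expect_true(all(s >= 0 & s <= 1))

  expect_error(specific_net_work(0, 0), "undefined")
  expect_error(specific_net_work(-1, 0), "non-negative")
})

test_that("SNW is scale-free", {
  set.seed(4)
  wp <- abs(rnorm(50)) + 0.01
  wn <- -abs(rnorm(50))
  for (c0 in c(0.1, 3, 1e4)) {
    expect_equal(specific_net_work(c0 * wp, c0 * wn),
                 specific_net_work(wp, wn), tolerance = 1e-12)
  }
})

test_that("tendon stress: time-averaged default and raw-impulse variant", {
  st <- tendon_stress(100, 0.5, peak_force = 500, csa = 1e-4)
  expect_equal(st$stress_mean, 2e6)           # (100/0.5)/1e-4 = 2 MPa
  expect_equal(st$stress_peak, 5e6)
  raw <- tendon_stress(100, 0.5, 500, 1e-4, raw_impulse = TRUE)
  expect_equal(raw$stress_mean, 1e6)          # 100/1e-4, Pa s
  expect_equal(tendon_stress(0, 0.5, 0, 1e-4)$stress_mean, 0)
  # peak stress ~ 110.6 MPa for a 6746 N peak on a 0.61 cm^2 tendon
  expect_equal(tendon_stress(1, 1, 6746, 0.61e-4)$stress_peak / 1e6, 110.6,
               tolerance = 0.01)
  expect_error(tendon_stress(10, 0.5, 10, 0), "csa")
})

test_that("strain, length change and Hookean energy chain together", {
  tc <- tendon_constants()
  expect_equal(tc$elastic_modulus, 819e6)
  expect_equal(tc$resilience, 0.93)
  s <- tendon_strain_and_dl(81.9e6, tc, 0.2)
  expect_equal(s$strain, 0.1)
  expect_equal(s$delta_l, 0.02)
  expect_equal(tendon_strain_and_dl(0, tc, 0.2)$delta_l, 0)
  expect_equal(tendon_strain_and_dl(819e6 * 0.05, tc, 0.2)$delta_l, 0.01)

  expect_equal(strain_energy(1000, 0.01, tc), 4.65)
  expect_equal(strain_energy(0, 0.01, tc), 0)
  expect_equal(strain_energy(2000, 0.02, tendon_constants(resilience = 1)), 20)

  # chain consistency: W = 0.5 * resilience * F * (F/(E CSA)) * L0
  set.seed(9)
  for (i in 1:20) {
    f <- runif(1, 100, 6000); csa <- runif(1, 0.4e-4, 0.9e-4)
    L0 <- runif(1, 0.15, 0.22)
    stress <- f / csa
    dl <- tendon_strain_and_dl(stress, tc, L0)$delta_l
    expect_equal(strain_energy(f, dl, tc),
                 0.5 * tc$resilience * f * (f / (tc$elastic_modulus * csa)) * L0,
                 tolerance = 1e-12)
  }
})

test_that("outcome assembly populates every field consistently", {
  subj <- generate_subject(noise_free_spec(), 1)
  kin <- tibble::tibble(
    gait = "run", step_index = 1L,
    work_pos_hip = 12, work_neg_hip = -3,
    work_pos_knee = 8, work_neg_knee = -8,
    work_pos_ankle = 20, work_neg_ankle = -10,
    force_impulse = 300, peak_force = 4000, grf_impulse = 260,
    r_ankle_ext = 0.09, stance_duration = 0.25, froude = 0.66
  )
  out <- assemble_outcomes(kin, subj)
  expect_equal(out$snw_knee, 0)
  expect_equal(out$snw_ankle, 1 / 3)
  expect_equal(out$energy_per_kg, out$energy / subj$body_mass)
  expect_equal(out$stress_mean_per_kg, out$stress_mean / subj$body_mass)
  expect_equal(out$delta_l, out$strain * subj$tendon_length)
  # energy field reproduces strain_energy() from the stored fields
  mean_force <- kin$force_impulse / kin$stance_duration
  expect_equal(out$energy, strain_energy(mean_force, out$delta_l))

  kin$froude <- NA_real_
  expect_error(assemble_outcomes(kin, subj), "froude")
})

test_that("a full synthetic step satisfies all outcome invariants", {
  spec <- noise_free_spec(gaits = "sprint")
  subj <- generate_subject(spec, 1)
  tr <- generate_trial(subj, "sprint", spec, seed = 77)
  out <- process_trial(tr$trial, subj, pipeline_config(filters = FALSE))
  expect_equal(nrow(out), 1)
  expect_true(all(out$snw_hip >= 0 & out$snw_hip <= 1))
  expect_true(all(out$snw_ankle >= 0 & out$snw_ankle <= 1))
  expect_gte(out$strain, 0)
  expect_gte(out$energy, 0)
  expect_equal(out$energy_per_kg * subj$body_mass, out$energy)
})

test_that("mass-specific stress decreases across moment-arm tertiles under injection", {
  spec <- cohort_spec(n_subjects = 9, steps_per_gait = 2, gaits = "run",
                      seed = 21, effect_injection = TRUE)
  coh <- generate_cohort(spec)
  out <- process_cohort(coh)
  d <- dplyr::left_join(out, coh$subjects[, c("subject_id", "at_moment_arm")],
                        by = "subject_id")
  d$tertile <- cut(d$at_moment_arm,
                   quantile(d$at_moment_arm, c(0, 1/3, 2/3, 1)),
                   include.lowest = TRUE, labels = FALSE)
  means <- tapply(d$stress_mean_per_kg, d$tertile, mean)
  expect_true(means[1] > means[2] && means[2] > means[3])
})
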