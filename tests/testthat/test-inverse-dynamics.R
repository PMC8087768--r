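test_that("joint angles reproduce geometric reference postures", {
  mk <- static_step(n = 5)
  ang <- joint_angles(mk)
  expect_equal(ang$knee, rep(180, 5))     # collinear hip-knee-ankle
  # vertical shank over a flat foot: neutral ankle
  expect_equal(ang$ankle, rep(90, 5))
  expect_equal(ang$hip, rep(180, 5))      # vertical thigh, neutral extension

  mk$mtp_y <- mk$ankle_y  # degenerate: zero-length check elsewhere
  mk2 <- static_step(n = 3)
  mk2$heel_x <- mk2$mtp_x; mk2$heel_y <- mk2$mtp_y
  expect_error(joint_angles(mk2), "Degenerate.*foot.*frame 1")
})

test_that("knee angle from marker vectors matches the law of cosines", {
  spec <- noise_free_spec(gaits = "run")
  subj <- generate_subject(spec, 1)
  out <- generate_trial(subj, "run", spec, seed = 9)
  mk <- out$trial$markers
  ang <- joint_angles(mk)
  Lt <- sqrt((mk$hip_x - mk$knee_x)^2 + (mk$hip_y - mk$knee_y)^2)
  Ls <- sqrt((mk$knee_x - mk$ankle_x)^2 + (mk$knee_y - mk$ankle_y)^2)
  D <- sqrt((mk$hip_x - mk$ankle_x)^2 + (mk$hip_y - mk$ankle_y)^2)
  loc <- acos(pmin(pmax((Lt^2 + Ls^2 - D^2) / (2 * Lt * Ls), -1), 1)) * 180 / pi
  expect_equal(ang$knee, loc, tolerance = 1e-9)
})

test_that("static posture reduces to the GRF lever at every joint", {
  step <- static_step(n = 40, mass = 70, cop_x = 0.12)
  m <- net_joint_moments(step, 70, 500, inertia = massless_inertia())
  fz <- 70 * 9.81
  expect_rel_equal(m$ankle, fz * (step$cop_x - step$ankle_x), 1e-9)
  # knee and hip: extensor-positive moments balancing the GRF lever
  expect_rel_equal(m$knee, -fz * (step$cop_x - step$knee_x), 1e-9)
  expect_rel_equal(m$hip, fz * (step$cop_x - step$hip_x), 1e-9)
})

test_that("zero GRF and stationary limb give zero moments", {
  step <- static_step(n = 30)
  step$fz <- 0
  m <- net_joint_moments(step, 70, 500, inertia = massless_inertia())
  expect_lt(max(abs(as.matrix(m[, c("ankle", "knee", "hip")]))), 1e-9)
})

test_that("COP outside the foot span triggers a warning, not an error", {
  step <- static_step(n = 30, cop_x = 0.40)
  expect_warning(net_joint_moments(step, 70, 500), "COP.*foot marker span")
})

test_that("noise-free synthetic trials reproduce forward ground truth", {
  spec <- noise_free_spec(gaits = c("walk", "sprint"))
  cfg <- pipeline_config(filters = FALSE)
  for (gait in spec$gaits) {
    subj <- generate_subject(spec, 2)
    out <- generate_trial(subj, gait, spec, seed = 31)
    res <- process_trial(out$trial, subj, cfg, keep_kinetics = TRUE)
    kin <- attr(res, "kinetics")[[1]]
    w <- out$truth$stance[1, ]
    idx <- w$start_frame:(w$end_frame - 1)
    for (j in c("ankle", "knee", "hip")) {
      expect_rel_equal(kin[[paste0("moment_", j)]],
                       out$truth$moments[[j]][idx], 1e-6)
    }
    expect_rel_equal(kin$force_ankle, out$truth$f_ankle[idx], 1e-6)
  }
})

test_that("muscle forces solve the bi-articular linear system", {
  model <- moment_arm_model()
  pcsa <- pcsa_partition()
  angles <- tibble::tibble(time = (0:2) / 500,
                           hip = c(160, 170, 175),
                           knee = c(140, 150, 160),
                           ankle = c(80, 95, 120))
  moments <- tibble::tibble(time = angles$time,
                            ankle = c(50, 120, 180),
                            knee = c(40, -25, 90),
                            hip = c(80, 60, -30))
  mf <- muscle_forces(moments, angles, model, pcsa)
  # independent oracle: solve the full 3x3 system per frame
  for (i in 1:3) {
    r_a <- moment_arm(model, "ankle", angles$ankle[i])
    r_k <- moment_arm(model, "knee", angles$knee[i])
    r_h <- moment_arm(model, "hip", angles$hip[i])
    r_gk <- moment_arm(model, "gastroc_knee", angles$knee[i])
    r_hk <- moment_arm(model, "hamstrings_knee", angles$knee[i])
    r_rf <- moment_arm(model, "rectus_femoris_hip", angles$hip[i])
    A <- rbind(c(r_a, 0, 0),
               c(-pcsa$gastroc * r_gk, r_k, -pcsa$hamstrings * r_hk),
               c(0, -pcsa$rectus_femoris * r_rf, r_h))
    f <- solve(A, c(moments$ankle[i], moments$knee[i], moments$hip[i]))
    expect_equal(unlist(mf[i, c("ankle", "knee", "hip")]), f,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("muscle forces: direct ratio without bi-articular terms, zero, homogeneity", {
  model <- moment_arm_model(ankle = c(c0 = 0.05, c1 = 0, c2 = 0, ref_deg = 90))
  angles <- tibble::tibble(time = 0, hip = 180, knee = 180, ankle = 90)
  moments <- tibble::tibble(time = 0, ankle = 100, knee = 0, hip = 0)
  mf <- muscle_forces(moments, angles, model, pcsa_partition(0, 0, 0))
  expect_equal(mf$ankle, 2000)            # 100 N m / 0.05 m

  z <- muscle_forces(dplyr::mutate(moments, ankle = 0), angles, model, pcsa_partition())
  expect_equal(unlist(z[, c("ankle", "knee", "hip")]), c(0, 0, 0),
               ignore_attr = TRUE)

  set.seed(5)
  angles <- tibble::tibble(time = (0:9) / 500, hip = runif(10, 150, 185),
                           knee = runif(10, 120, 180), ankle = runif(10, 70, 150))
  moments <- tibble::tibble(time = angles$time, ankle = rnorm(10, 80, 40),
                            knee = rnorm(10, 40, 40), hip = rnorm(10, 50, 40))
  f1 <- muscle_forces(moments, angles)
  f3 <- muscle_forces(dplyr::mutate(moments, dplyr::across(c(ankle, knee, hip), ~3 * .x)),
                      angles)
  expect_equal(3 * f1$ankle, f3$ankle, tolerance = 1e-12)
  expect_equal(3 * f1$knee, f3$knee, tolerance = 1e-12)
  expect_equal(3 * f1$hip, f3$hip, tolerance = 1e-12)
})

test_that("external moment arm reduces to closed forms", {
  n <- 101
  G <- rep(900, n); r0 <- rep(0.05, n)
  expect_equal(external_moment_arm_ankle(G, r0, 3 * G, 500), 0.05 / 3)
  # F = GRF: R is the GRF-weighted mean of r
  set.seed(2)
  r <- runif(n, 0.04, 0.06)
  g <- 800 + 200 * sin(seq(0, pi, length.out = n))
  num <- trapz_integral(g * r, 500)
  den <- trapz_integral(g, 500)
  expect_equal(external_moment_arm_ankle(g, r, g, 500), num / den, tolerance = 1e-12)
  expect_error(external_moment_arm_ankle(G, r0, rep(0, n), 500), "impulse is zero")
})

test_that("work decomposition is consistent and signed", {
  n <- 501  # 1 s at 500 Hz
  w <- joint_power_work(rep(10, n), rep(1, n), 500)
  expect_equal(w$work_pos, 10, tolerance = 1e-9)
  expect_equal(w$work_neg, 0)

  # antisymmetric angular velocity about mid-stance, constant moment
  om <- seq(-1, 1, length.out = n)
  w2 <- joint_power_work(rep(5, n), om, 500)
  expect_equal(w2$work_pos, -w2$work_neg, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:5) {
    M <- rnorm(200); om <- rnorm(200)
    w3 <- joint_power_work(M, om, 500)
    expect_equal(w3$work_pos + w3$work_neg, trapz_integral(M * om, 500),
                 tolerance = 1e-9)
    expect_gte(w3$work_pos, 0)
    expect_lte(w3$work_neg, 0)
  }
})

test_that("Froude number follows the dynamic similarity scaling", {
  expect_equal(froude_number(1, 1), 1 / 9.81)
  expect_equal(froude_number(3.132, 1.0), 1, tolerance = 1e-3)
  expect_equal(froude_number(2 * 1.3, 0.9), 4 * froude_number(1.3, 0.9))
  expect_error(froude_number(0, 1), "positive")
})
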