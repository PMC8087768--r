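#' Segment inertial parameters (Winter anthropometric proportions)
#'
#' Per-segment mass fraction of body mass, centre-of-mass position as a
#' fraction of segment length from the proximal end, and radius of gyration
#' about the COM as a fraction of segment length. Defaults follow the
#' standard anthropometric proportions used in gait analysis (foot 1.45% of
#' body mass, shank 4.65%, thigh 10.0%); all are overridable.
#'
#' @param foot,shank,thigh Named numeric vectors with elements `mass_frac`,
#'   `com_frac`, `gyration_frac`.
#' @return A tibble with one row per segment.
#' @export
segment_inertia <- function(
    foot  = c(mass_frac = 0.0145, com_frac = 0.50,  gyration_frac = 0.475),
    shank = c(mass_frac = 0.0465, com_frac = 0.433, gyration_frac = 0.302),
    thigh = c(mass_frac = 0.100,  com_frac = 0.433, gyration_frac = 0.323)) {
  tbl <- bind_rows(
    tibble(segment = "foot",  !!!as.list(foot)),
    tibble(segment = "shank", !!!as.list(shank)),
    tibble(segment = "thigh", !!!as.list(thigh))
  )
  frac <- c(tbl$com_frac, tbl$gyration_frac)
  if (any(frac <= 0 | frac >= 1)) abort("COM and gyration fractions must lie in (0, 1).")
  if (sum(tbl$mass_frac) >= 1) abort("Segment mass fractions must sum to less than 1.")
  tbl
}

#' Angle-dependent extensor moment arm model
#'
#' Extensor (and bi-articular flexor) muscle moment arms vary with joint
#' angle. Each muscle gets a quadratic polynomial in the joint angle
#' (degrees, measured from a reference angle) returning the arm in metres,
#' following the common literature parameterisations for the hip and knee
#' extensors and the plantarflexors. Coefficients are deliberately
#' configurable because published fits differ between sources; the defaults
#' are representative adult values. Polynomials are linearly rescaled per
#' subject: the ankle polynomial so that its value at the 90 degree neutral
#' angle equals the subject's measured (static) Achilles tendon moment arm,
#' the others by the subject's hip height relative to a 0.88 m reference.
#'
#' @param ankle,knee,hip,gastroc_knee,hamstrings_knee,rectus_femoris_hip
#'   Numeric vectors `c(c0, c1, c2, ref_deg)`: arm(theta) =
#'   `c0 + c1 (theta - ref) + c2 (theta - ref)^2` metres, theta in degrees.
#' @return An object of class `moment_arm_model`.
#' @export
moment_arm_model <- function(
    ankle              = c(c0 = 0.052, c1 = 1.2e-4,  c2 = -1.5e-6, ref_deg = 90),
    knee               = c(c0 = 0.041, c1 = -8.0e-5, c2 = -3.0e-7, ref_deg = 180),
    hip                = c(c0 = 0.065, c1 = 2.0e-5,  c2 = 0,       ref_deg = 180),
    gastroc_knee       = c(c0 = 0.020, c1 = 1.0e-5,  c2 = 0,       ref_deg = 180),
    hamstrings_knee    = c(c0 = 0.025, c1 = -2.0e-5, c2 = 0,       ref_deg = 180),
    rectus_femoris_hip = c(c0 = 0.035, c1 = 1.0e-5,  c2 = 0,       ref_deg = 180)) {
  model <- list(ankle = ankle, knee = knee, hip = hip,
                gastroc_knee = gastroc_knee, hamstrings_knee = hamstrings_knee,
                rectus_femoris_hip = rectus_femoris_hip)
  for (nm in names(model)) {
    if (length(model[[nm]]) != 4) abort(sprintf("`%s` needs c(c0, c1, c2, ref_deg).", nm))
  }
  structure(model, class = "moment_arm_model")
}

#' Evaluate a moment-arm polynomial
#'
#' @param model A [moment_arm_model()].
#' @param muscle One of the muscle names of the model.
#' @param angle_deg Joint angle series in degrees.
#' @param scale Subject scaling factor (dimensionless), default 1.
#' @return Moment arm series in metres.
#' @export
moment_arm <- function(model, muscle, angle_deg, scale = 1) {
  cf <- model[[muscle]]
  if (is.null(cf)) abort(sprintf("Unknown muscle '%s' in moment-arm model.", muscle))
  d <- angle_deg - cf[["ref_deg"]]
  scale * (cf[["c0"]] + cf[["c1"]] * d + cf[["c2"]] * d^2)
}

#' PCSA partition of muscle-group force
#'
#' Bi-articular corrections apportion group force to a spanning muscle in
#' proportion to its physiological cross-sectional area: the gastrocnemius
#' fraction of the plantarflexors, the hamstrings fraction of the hip
#' extensors, and the rectus femoris fraction of the knee extensors.
#' Defaults are representative adult PCSA shares and are configurable.
#'
#' @param gastroc,hamstrings,rectus_femoris Fractions in `[0, 1)`.
#' @return A named list.
#' @export
pcsa_partition <- function(gastroc = 0.34, hamstrings = 0.40, rectus_femoris = 0.21) {
  v <- c(gastroc = gastroc, hamstrings = hamstrings, rectus_femoris = rectus_femoris)
  if (any(v < 0 | v >= 1)) abort("PCSA fractions must lie in [0, 1).")
  as.list(v)
}

# ---------------------------------------------------------------------------
# Kinematic geometry

required_markers <- c("hip", "knee", "ankle", "mtp", "heel")

marker_col <- function(markers, name, axis) {
  col <- paste0(name, "_", axis)
  if (!col %in% names(markers)) abort(sprintf("Missing marker column '%s'.", col))
  markers[[col]]
}

# CCW angle (rad) of the vector from (x1,y1) to (x2,y2); errors on
# degenerate zero-length segments, naming the first bad frame.
segment_phi <- function(x1, y1, x2, y2, what) {
  dx <- x2 - x1
  dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  bad <- which(len < 1e-9)
  if (length(bad) > 0) {
    abort(sprintf("Degenerate (zero-length) %s segment at frame %d.", what, bad[1]))
  }
  unwrap_angle(atan2(dy, dx))
}

#' Joint angles from sagittal marker trajectories
#'
#' Computes included joint angles (degrees) at each frame from adjacent
#' segment vectors:
#' * **ankle**: angle between the shank line (ankle to knee) and the foot
#'   line (heel to metatarsal head); 90 degrees is neutral and
#'   plantarflexion increases the angle (a strongly plantarflexed foot sits
#'   near 160 degrees).
#' * **knee**: included angle at the knee; 180 degrees when hip, knee and
#'   ankle are collinear, flexion decreases it.
#' * **hip**: thigh angle relative to the (assumed vertical) trunk;
#'   180 degrees at neutral extension, flexion decreases it.
#'
#' Angles are continuous (unwrapped) so they can be differentiated.
#'
#' @param markers A data frame with columns `time` and `<name>_x`, `<name>_y`
#'   for markers `hip`, `knee`, `ankle`, `mtp`, `heel` (metres).
#' @return A tibble with columns `time`, `hip`, `knee`, `ankle` (degrees).
#' @export
joint_angles <- function(markers) {
  for (m in required_markers) {
    marker_col(markers, m, "x")
    marker_col(markers, m, "y")
  }
  gx <- function(m) marker_col(markers, m, "x")
  gy <- function(m) marker_col(markers, m, "y")

  phi_foot  <- segment_phi(gx("heel"), gy("heel"), gx("mtp"), gy("mtp"), "foot")
  phi_shank <- segment_phi(gx("ankle"), gy("ankle"), gx("knee"), gy("knee"), "shank")
  phi_thigh <- segment_phi(gx("knee"), gy("knee"), gx("hip"), gy("hip"), "thigh")

  ankle <- (phi_shank - phi_foot) * 180 / pi
  knee  <- 180 - (phi_thigh - phi_shank) * 180 / pi
  hip   <- 270 - phi_thigh * 180 / pi
  tibble(time = markers$time, hip = hip, knee = knee, ankle = ankle)
}

# Subject-specific polynomial scales (see moment_arm_model docs).
subject_arm_scales <- function(subject, model, reference_hip_height = 0.88) {
  neutral <- moment_arm(model, "ankle", 90, scale = 1)
  list(
    ankle = subject$at_moment_arm / neutral,
    other = subject$hip_height / reference_hip_height
  )
}

# ---------------------------------------------------------------------------
# Free-body recursion

# Planar cross product (z component) of r x F.
cross2 <- function(rx, ry, fx, fy) rx * fy - ry * fx

# Internal workhorse shared by net_joint_moments(): given marker series,
# force series (already at the kinematic rate) and subject scalars, run the
# distal-to-proximal Newton-Euler recursion. Returns per-frame CCW joint
# moments mapped to the extensor-positive reporting convention
# (plantarflexion positive at the ankle).
free_body_moments <- function(markers, fz, fx, cop_x, rate, body_mass,
                              inertia = segment_inertia(), g = GRAVITY) {
  gx <- function(m) marker_col(markers, m, "x")
  gy <- function(m) marker_col(markers, m, "y")
  n <- nrow(markers)

  seg <- function(name) inertia[inertia$segment == name, ]

  # segment endpoint series: foot runs heel -> mtp with the ankle as its
  # proximal joint; shank knee -> ankle; thigh hip -> knee
  ends <- list(
    foot  = list(px = gx("heel"), py = gy("heel"), dx = gx("mtp"),  dy = gy("mtp")),
    shank = list(px = gx("knee"), py = gy("knee"), dx = gx("ankle"), dy = gy("ankle")),
    thigh = list(px = gx("hip"),  py = gy("hip"),  dx = gx("knee"),  dy = gy("knee"))
  )

  seg_state <- lapply(names(ends), function(s) {
    e <- ends[[s]]
    p <- seg(s)
    cx <- e$px + p$com_frac * (e$dx - e$px)
    cy <- e$py + p$com_frac * (e$dy - e$py)
    len <- mean(sqrt((e$dx - e$px)^2 + (e$dy - e$py)^2))
    phi <- segment_phi(e$px, e$py, e$dx, e$dy, s)
    list(
      mass = p$mass_frac * body_mass,
      I = p$mass_frac * body_mass * (p$gyration_frac * len)^2,
      cx = cx, cy = cy,
      ax = finite_diff_accel(cx, rate),
      ay = finite_diff_accel(cy, rate),
      alpha = finite_diff_accel(phi, rate)
    )
  })
  names(seg_state) <- names(ends)

  # --- foot free body: GRF at the COP, weight, ankle reaction ------------
  f <- seg_state$foot
  Fax <- f$mass * f$ax - fx
  Fay <- f$mass * f$ay - fz + f$mass * g
  Ma_ccw <- f$I * f$alpha -
    cross2(cop_x - f$cx, 0 - f$cy, fx, fz) -
    cross2(gx("ankle") - f$cx, gy("ankle") - f$cy, Fax, Fay)

  # --- shank free body: ankle reaction (negated), weight, knee reaction --
  s <- seg_state$shank
  Fkx <- s$mass * s$ax + Fax
  Fky <- s$mass * s$ay + Fay + s$mass * g
  Mk_ccw <- s$I * s$alpha + Ma_ccw -
    cross2(gx("ankle") - s$cx, gy("ankle") - s$cy, -Fax, -Fay) -
    cross2(gx("knee") - s$cx, gy("knee") - s$cy, Fkx, Fky)

  # --- thigh free body ----------------------------------------------------
  t <- seg_state$thigh
  Fhx <- t$mass * t$ax + Fkx
  Fhy <- t$mass * t$ay + Fky + t$mass * g
  Mh_ccw <- t$I * t$alpha + Mk_ccw -
    cross2(gx("knee") - t$cx, gy("knee") - t$cy, -Fkx, -Fky) -
    cross2(gx("hip") - t$cx, gy("hip") - t$cy, Fhx, Fhy)

  # extensor-positive reporting: in statics the ankle moment reduces to
  # fz * (COPx - ankle_x), positive with the COP anterior to the ankle
  tibble(
    time = markers$time,
    ankle = -Ma_ccw,
    knee = Mk_ccw,
    hip = -Mh_ccw
  )
}

#' Net joint moments by the free-body (link-segment) method
#'
#' Distal-to-proximal Newton-Euler recursion in the sagittal plane: the
#' ankle moment from the foot free body (GRF applied at the centre of
#' pressure, foot weight and inertial terms), then the knee from the shank,
#' then the hip from the thigh. Mediolateral forces are outside the planar
#' model. Reported moments are extensor-positive (plantarflexor-positive at
#' the ankle): in static standing the ankle moment equals
#' `fz * (COPx - ankle_x)`.
#'
#' A warning (not an error) is emitted if the COP strays more than 5 cm
#' outside the heel-to-toe marker span, which usually indicates a
#' force-plate/kinematics registration problem.
#'
#' @param step A data frame with one row per kinematic frame: `time`, the
#'   ten marker columns (see [joint_angles()]), `fz`, `fx` (N) and
#'   `cop_x` (m), all synchronized at `rate`.
#' @param body_mass Subject body mass (kg).
#' @param rate Kinematic sampling rate (Hz).
#' @param inertia A [segment_inertia()] table.
#' @param g Gravitational acceleration (m/s^2).
#' @return A tibble `time`, `ankle`, `knee`, `hip` of net moments (N m).
#' @export
net_joint_moments <- function(step, body_mass, rate, inertia = segment_inertia(),
                              g = GRAVITY) {
  stopifnot_scalar_pos(body_mass, "body_mass")
  needed <- c("fz", "fx", "cop_x")
  miss <- setdiff(needed, names(step))
  if (length(miss) > 0) abort(sprintf("Missing force column '%s'.", miss[1]))

  loaded <- step$fz > 1
  if (any(loaded)) {
    lo <- pmin(step$heel_x, step$mtp_x) - 0.05
    hi <- pmax(step$heel_x, step$mtp_x) + 0.05
    out <- loaded & (step$cop_x < lo | step$cop_x > hi)
    if (any(out)) {
      warn(sprintf("COP falls > 5 cm outside the foot marker span on %d frame(s) (first: %d).",
                   sum(out), which(out)[1]))
    }
  }
  free_body_moments(step, step$fz, step$fx, step$cop_x, rate, body_mass,
                    inertia = inertia, g = g)
}

#' Extensor muscle forces from net moments with bi-articular corrections
#'
#' Solves the linear system linking net joint moments to extensor group
#' forces, subtracting the flexor actions of the bi-articular muscles
#' (gastrocnemius at the knee, hamstrings at the knee, rectus femoris at the
#' hip), each carrying its PCSA share of the parent group's force:
#'
#' * ankle: `F_ankle = M_ankle / r_ankle`
#' * knee: `M_knee = F_knee r_knee - F_G r_G,knee - F_H r_H,knee`
#' * hip: `M_hip = F_hip r_hip - F_RF r_RF,hip`
#'
#' with `F_G = c_G F_ankle`, `F_H = c_H F_hip`, `F_RF = c_RF F_knee`.
#' After the ankle is solved, the knee/hip pair is a 2x2 linear system
#' solved in closed form per frame. The solution is homogeneous of degree
#' one in the moments.
#'
#' @param moments Tibble from [net_joint_moments()] (`time`, `ankle`,
#'   `knee`, `hip`, N m).
#' @param angles Tibble from [joint_angles()] (degrees), same frames.
#' @param model A [moment_arm_model()].
#' @param pcsa A [pcsa_partition()].
#' @param arm_scales List with elements `ankle` and `other` (see
#'   [moment_arm_model()]); default no scaling.
#' @return A tibble `time`, `ankle`, `knee`, `hip` of muscle forces (N),
#'   plus the instantaneous `r_ankle` arm (m) used at each frame.
#' @export
muscle_forces <- function(moments, angles, model = moment_arm_model(),
                          pcsa = pcsa_partition(),
                          arm_scales = list(ankle = 1, other = 1)) {
  r_a  <- moment_arm(model, "ankle", angles$ankle, arm_scales$ankle)
  r_k  <- moment_arm(model, "knee", angles$knee, arm_scales$other)
  r_h  <- moment_arm(model, "hip", angles$hip, arm_scales$other)
  r_gk <- moment_arm(model, "gastroc_knee", angles$knee, arm_scales$other)
  r_hk <- moment_arm(model, "hamstrings_knee", angles$knee, arm_scales$other)
  r_rf <- moment_arm(model, "rectus_femoris_hip", angles$hip, arm_scales$other)

  for (nm in c("ankle", "knee", "hip")) {
    r <- switch(nm, ankle = r_a, knee = r_k, hip = r_h)
    bad <- which(r <= 0)
    if (length(bad) > 0) {
      abort(sprintf("Non-positive %s extensor moment arm at frame %d.", nm, bad[1]))
    }
  }

  f_ankle <- moments$ankle / r_a
  f_g <- pcsa$gastroc * f_ankle
  # 2x2 system in (F_knee, F_hip):
  #   r_k F_k - c_H r_hk F_h = M_k + F_G r_gk
  #  -c_RF r_rf F_k + r_h F_h = M_h
  rhs_k <- moments$knee + f_g * r_gk
  det <- r_k * r_h - pcsa$hamstrings * r_hk * pcsa$rectus_femoris * r_rf
  f_knee <- (rhs_k * r_h + pcsa$hamstrings * r_hk * moments$hip) / det
  f_hip  <- (moments$hip * r_k + pcsa$rectus_femoris * r_rf * rhs_k) / det

  tibble(time = moments$time, ankle = f_ankle, knee = f_knee, hip = f_hip,
         r_ankle = r_a)
}

#' Impulse-averaged external moment arm of the GRF at the ankle
#'
#' The average lever of the ground reaction force about the ankle over a
#' support phase, defined as the ratio of the GRF-weighted tendon moment arm
#' impulse to the ankle muscle force impulse:
#' `R = integral(GRF * r_ankle dt) / integral(F_ankle dt)`.
#'
#' @param grf Resultant GRF magnitude series (N).
#' @param r_ankle Instantaneous tendon moment arm series (m).
#' @param f_ankle Ankle muscle force series (N).
#' @param rate Sampling rate (Hz).
#' @param window Stance window (see [trapz_integral()]).
#' @return The external moment arm (m).
#' @export
external_moment_arm_ankle <- function(grf, r_ankle, f_ankle, rate, window = NULL) {
  denom <- trapz_integral(f_ankle, rate, window)
  if (abs(denom) < 1e-12) {
    abort("Undefined external moment arm: the ankle force impulse is zero.")
  }
  trapz_integral(grf * r_ankle, rate, window) / denom
}

#' Joint power and positive/negative work over a stance window
#'
#' Power is `M * omega` per frame; positive work integrates the positive
#' part of power over the window and negative work the negative part, so
#' `work_pos >= 0 >= work_neg` and their sum equals the integral of power.
#'
#' @param moment Net joint moment series (N m), extensor-positive.
#' @param omega Joint angular velocity series (rad/s) in the same sign
#'   convention.
#' @param rate Sampling rate (Hz).
#' @param window Stance window (see [trapz_integral()]).
#' @return A list with `power` (W, full series), `work_pos` and `work_neg` (J).
#' @export
joint_power_work <- function(moment, omega, rate, window = NULL) {
  power <- moment * omega
  list(
    power = power,
    work_pos = trapz_integral(pmax(power, 0), rate, window),
    work_neg = trapz_integral(pmin(power, 0), rate, window)
  )
}

#' Froude number
#'
#' Dimensionless squared speed, `v^2 / (g * hip_height)`, used to compare
#' gaits across body sizes (dynamic similarity).
#'
#' @param speed Mean progression speed (m/s).
#' @param hip_height Standing hip height (m).
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @return Dimensionless Froude number.
#' @examples
#' froude_number(3.132, 1.0)  # 1
#' @export
froude_number <- function(speed, hip_height, g = GRAVITY) {
  if (any(speed <= 0) || any(hip_height <= 0)) {
    abort("`speed` and `hip_height` must be positive.")
  }
  speed^2 / (g * hip_height)
}
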