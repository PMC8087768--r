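#' Tendon material constants
#'
#' Elastic modulus and resilience used by the Hookean tendon model. The
#' defaults are an elastic modulus of 819 MPa (mean of published human
#' Achilles tendon material tests) and a resilience of 0.93 (fraction of
#' stored elastic energy returned).
#'
#' @param elastic_modulus Elastic modulus in Pa. Default `819e6`.
#' @param resilience Fraction of stored energy returned, in `(0, 1]`.
#' @return A named list of class `tendon_constants`.
#' @export
tendon_constants <- function(elastic_modulus = 819e6, resilience = 0.93) {
  stopifnot_scalar_pos(elastic_modulus, "elastic_modulus")
  if (resilience <= 0 || resilience > 1) abort("`resilience` must lie in (0, 1].")
  structure(list(elastic_modulus = elastic_modulus, resilience = resilience),
            class = "tendon_constants")
}

#' Specific net work (SNW)
#'
#' The spring statistic for a joint over one support phase:
#' `|W+ + W-| / (|W+| + |W-|)`. A value of 0 means equal energy absorbed
#' and returned (a perfect spring); 1 means purely positive or purely
#' negative work (a pure motor or brake).
#'
#' @param work_pos Positive joint work (J), `>= 0`.
#' @param work_neg Negative joint work (J), `<= 0`.
#' @return SNW in `[0, 1]`. Vectorized.
#' @examples
#' specific_net_work(5, -5)  # 0, perfect spring
#' specific_net_work(5, 0)   # 1, pure motor
#' specific_net_work(3, -1)  # 0.5
#' @export
specific_net_work <- function(work_pos, work_neg) {
  if (any(work_pos < 0)) abort("`work_pos` must be non-negative.")
  if (any(work_neg > 0)) abort("`work_neg` must be non-positive.")
  tot <- abs(work_pos) + abs(work_neg)
  if (any(tot == 0)) {
    abort("SNW is undefined when both positive and negative work are zero.")
  }
  abs(work_pos + work_neg) / tot
}

#' Tendon stress from the stance force impulse
#'
#' Mean tendon stress scales the ankle muscle force imparted over the whole
#' support phase to the tendon cross-sectional area. By default the force
#' impulse is divided by the stance duration (time-averaged force) before
#' dividing by CSA, which yields stress in Pa; with `raw_impulse = TRUE`
#' the impulse itself is divided by CSA (units Pa s), the literal
#' impulse-over-area form. Peak stress is the peak instantaneous force over
#' CSA and is the quantity comparable to published tendon failure stresses.
#'
#' @param force_impulse Ankle muscle force impulse over stance (N s).
#' @param stance_duration Stance duration (s).
#' @param peak_force Peak instantaneous ankle muscle force (N).
#' @param csa Tendon cross-sectional area (m^2).
#' @param raw_impulse If `TRUE`, return `force_impulse / csa` (Pa s) as the
#'   mean-stress field instead of the time-averaged form. Default `FALSE`.
#' @return A list with `stress_mean` and `stress_peak` (Pa; Pa s for the
#'   mean when `raw_impulse = TRUE`).
#' @export
tendon_stress <- function(force_impulse, stance_duration, peak_force, csa,
                          raw_impulse = FALSE) {
  stopifnot_scalar_pos(csa, "csa")
  stopifnot_scalar_pos(stance_duration, "stance_duration")
  mean_force <- if (raw_impulse) force_impulse else force_impulse / stance_duration
  list(stress_mean = mean_force / csa, stress_peak = peak_force / csa)
}

#' Tendon strain and length change
#'
#' Hookean strain is stress over the elastic modulus; the length change is
#' strain times the resting tendon length.
#'
#' @param stress Tendon stress (Pa).
#' @param constants A [tendon_constants()].
#' @param resting_length Resting tendon length (m).
#' @return A list with `strain` (dimensionless) and `delta_l` (m).
#' @export
tendon_strain_and_dl <- function(stress, constants = tendon_constants(),
                                 resting_length) {
  stopifnot_scalar_pos(resting_length, "resting_length")
  strain <- stress / constants$elastic_modulus
  list(strain = strain, delta_l = strain * resting_length)
}

#' Elastic strain energy stored in the tendon
#'
#' Hookean spring energy `W = 0.5 * F * delta_L`, discounted by the tendon
#' resilience (fraction of stored energy actually returned).
#'
#' @param force Tendon force measure (N); by convention the same
#'   time-averaged ankle force used for mean stress.
#' @param delta_l Tendon length change (m).
#' @param constants A [tendon_constants()].
#' @return Stored (recoverable) elastic energy (J).
#' @examples
#' strain_energy(1000, 0.01)  # 4.65 J at the default 0.93 resilience
#' @export
strain_energy <- function(force, delta_l, constants = tendon_constants()) {
  if (any(force < 0) || any(delta_l < 0)) abort("`force` and `delta_l` must be non-negative.")
  0.5 * force * delta_l * constants$resilience
}

#' Assemble the per-step tendon outcome record
#'
#' Combines the per-step joint kinetics summary with subject morphometrics
#' and tendon constants into one outcome row: Froude number, SNW per joint,
#' force impulse, external moment arm, mean and peak tendon stress, strain,
#' length change, stored elastic energy, and the mass-specific variants
#' (divided by body mass).
#'
#' Steps whose ankle work decomposition is entirely zero have no defined
#' SNW; such steps are flagged (`snw_defined = FALSE`, SNW fields `NA`) and
#' are excluded from downstream statistics.
#'
#' @param kin A one-row data frame (or named list) with fields
#'   `work_pos_hip`, `work_neg_hip`, `work_pos_knee`, `work_neg_knee`,
#'   `work_pos_ankle`, `work_neg_ankle` (J), `force_impulse` (N s),
#'   `peak_force` (N), `grf_impulse` (N s), `r_ankle_ext` (m),
#'   `stance_duration` (s), `froude`, `step_index`, `gait`.
#' @param subject One row of a subject morphometrics table (see
#'   [read_subject_config()] or [generate_subject()]).
#' @param constants A [tendon_constants()].
#' @param raw_impulse Passed to [tendon_stress()].
#' @return A one-row tibble, one step of the outcome table.
#' @export
assemble_outcomes <- function(kin, subject, constants = tendon_constants(),
                              raw_impulse = FALSE) {
  needed <- c("work_pos_hip", "work_neg_hip", "work_pos_knee", "work_neg_knee",
              "work_pos_ankle", "work_neg_ankle", "force_impulse", "peak_force",
              "grf_impulse", "r_ankle_ext", "stance_duration", "froude",
              "step_index", "gait")
  for (f in needed) {
    if (is.null(kin[[f]]) || is.na(kin[[f]])) {
      abort(sprintf("Missing upstream value '%s' for outcome assembly.", f))
    }
  }
  snw_of <- function(wp, wn) {
    if (abs(wp) + abs(wn) == 0) NA_real_ else specific_net_work(wp, wn)
  }
  snw_hip <- snw_of(kin$work_pos_hip, kin$work_neg_hip)
  snw_knee <- snw_of(kin$work_pos_knee, kin$work_neg_knee)
  snw_ankle <- snw_of(kin$work_pos_ankle, kin$work_neg_ankle)

  st <- tendon_stress(kin$force_impulse, kin$stance_duration, kin$peak_force,
                      subject$tendon_csa, raw_impulse = raw_impulse)
  sl <- tendon_strain_and_dl(st$stress_mean, constants, subject$tendon_length)
  mean_force <- if (raw_impulse) kin$force_impulse else kin$force_impulse / kin$stance_duration
  energy <- strain_energy(max(mean_force, 0), max(sl$delta_l, 0), constants)

  tibble(
    subject_id = subject$subject_id,
    gait = kin$gait,
    step_index = kin$step_index,
    froude = kin$froude,
    snw_hip = snw_hip,
    snw_knee = snw_knee,
    snw_ankle = snw_ankle,
    snw_defined = !is.na(snw_ankle),
    force_impulse = kin$force_impulse,
    grf_impulse = kin$grf_impulse,
    r_ankle_ext = kin$r_ankle_ext,
    stress_mean = st$stress_mean,
    stress_peak = st$stress_peak,
    strain = sl$strain,
    delta_l = sl$delta_l,
    energy = energy,
    energy_per_kg = energy / subject$body_mass,
    stress_mean_per_kg = st$stress_mean / subject$body_mass
  )
}
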