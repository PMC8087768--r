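---
title: "Methods: inverse dynamics and Achilles tendon spring mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse dynamics and Achilles tendon spring mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitspring)
```

## The scientific problem

The Achilles tendon (AT) stores elastic strain energy during the support
phase of running gaits and returns most of it at push-off. A long-standing
biomechanical model predicts that a *shorter* AT moment arm (the lever of
the calcaneal tuberosity about the ankle joint centre) forces the
plantarflexors to generate larger forces for the same joint moment
(`F = M / r`), imparting larger loads to the tendon and therefore storing
more elastic energy. gaitspring implements the full analysis chain needed
to test that model on sagittal-plane gait trials:

1. **Signal conditioning** — zero-lag Butterworth low-pass filtering,
   force-to-kinematics synchronization, stance detection;
2. **Inverse dynamics** — net joint moments by the planar free-body
   (link-segment) recursion, extensor muscle forces with bi-articular
   corrections, joint power and work;
3. **Tendon mechanics** — the specific net work (SNW) spring statistic,
   tendon stress, strain, length change and Hookean strain energy;
4. **Statistics** — one-tailed Pearson correlations and a
   subject-random-intercept mixed model on z-scored variates;
5. **Synthetic gait generation** — a forward-constructed trial simulator
   with a ground-truth channel, so every downstream stage is testable
   without motion-capture data.

## Coordinate and sign conventions

The model is two-dimensional: `x` points along the direction of travel,
`y` up. Mediolateral forces are outside the planar model. Net joint
moments are reported extensor-positive (plantarflexor-positive at the
ankle): in static standing the ankle moment equals
`fz * (COPx - ankle_x)`, positive with the centre of pressure anterior to
the ankle. Included joint angles are in degrees at the interfaces (the
ankle is 90° at neutral, larger in plantarflexion; knee and hip are 180°
when straight) and radians internally when differentiated. Gravitational
acceleration is 9.81 m/s².

Joint power uses the identity that the power delivered by a joint moment
to its two adjacent segments is `M * (omega_distal - omega_proximal)`;
with angles and moments in a shared joint convention this is simply
`M * d(theta)/dt`, which is what the pipeline computes. Positive and
negative work integrate the positive and negative parts of power
separately, so `work_pos + work_neg` always equals the integral of power.

## Filtering and differentiation

"Fourth-order zero-lag Butterworth" is interpreted the way gait
laboratories conventionally report it: a second-order pass applied forward
and then backward, giving a fourth-order magnitude response and zero phase
lag. A configuration switch (`order_per_pass = "full"`) selects the
stated order per direction instead. Coefficients come from
`signal::butter()`; the forward-backward pass itself uses odd-reflection
end padding with steady-state initial conditions, so a constant series is
returned exactly and short series acquire no edge transients. Defaults are
6 Hz for kinematics and 100 Hz for force data. Whether the COP should be
filtered like the force channels is genuinely open; the default filters it
(`filter_cop = TRUE`), since an unfiltered COP would reintroduce noise
into the ankle lever.

Note one unavoidable property of any Butterworth anti-aliasing filter: at
its own cutoff the response is −3 dB per pass, so a sinusoid *at* the
cutoff frequency loses roughly 40% of its amplitude after a zero-lag
pass. Passband components (≲ half the cutoff) are preserved within a few
percent, which is the regime the force waveforms occupy.

Accelerations use the second-order central difference
`(x[i+1] - 2 x[i] + x[i-1]) * rate^2` with one-sided second-order stencils
at the ends — exact for quadratic trajectories; angular velocity uses the
matching first-derivative stencils.

Force plates sample at an integer multiple of the camera rate (1 kHz vs
500 Hz by default). Downsampling keeps every k-th sample starting at the
first, so retained samples fall exactly on kinematic frame times; the
100 Hz force filter acts as the anti-aliasing stage.

Stance detection is not specified by most papers; the package uses a
configurable rule: maximal runs with vertical GRF ≥ 20 N lasting at least
50 ms. Both numbers are exposed in `pipeline_config()`.

## Inverse dynamics

Segment inertial parameters default to the standard anthropometric
proportions (foot 1.45%, shank 4.65%, thigh 10.0% of body mass, with the
usual COM and radius-of-gyration fractions) and are fully overridable.
Moment arms vary with joint angle through configurable quadratic
polynomials with representative literature defaults; published fits differ
between sources, so the coefficients are deliberately part of the
configuration surface rather than hard-coded. Each subject's ankle
polynomial is rescaled so its value at the neutral 90° angle equals the
subject's measured static AT moment arm; hip and knee polynomials scale
with hip height.

Muscle forces solve the linear system linking net moments to extensor
group forces with bi-articular flexor corrections (gastrocnemius at the
knee, hamstrings at the knee, rectus femoris at the hip), each muscle
carrying its PCSA share of its parent group's force (defaults 0.34, 0.40,
0.21). After `F_ankle = M_ankle / r_ankle`, the knee-hip pair is a 2×2
linear system solved in closed form per frame; the solution is
homogeneous of degree one in the moments, which the tests exploit.

The impulse-averaged external moment arm of the GRF at the ankle is
`R = ∫ GRF · r dt / ∫ F_ankle dt` over stance. The numerator's lever is
the instantaneous *tendon* moment arm, exactly as the defining equation is
written in the source literature, even though `R` describes the external
lever; because this is arguably a transcription quirk, a configuration
flag (`eq_arm_numerator = "external"`) substitutes the instantaneous
external lever `COPx - ankle_x` instead. Neither reading is asserted to
be the "true" one.

## Tendon mechanics

SNW for a joint over one stance is `|W+ + W-| / (|W+| + |W-|)`: 0 for a
perfect spring (equal absorption and return), 1 for a pure motor or brake.
Steps whose work decomposition is entirely zero have no defined SNW and
are flagged and excluded from statistics.

Tendon stress is the force imparted over the whole stance scaled to the
tendon's cross-sectional area. The defining impulse-over-area expression
has units of Pa·s; to report stress in Pa the default divides the impulse
by the stance duration first (time-averaged force), with the literal
impulse form available behind `stress_raw_impulse = TRUE`. The same force
measure feeds the energy estimate so that the stored energy is in joules.
Peak stress (peak instantaneous force / CSA) is reported alongside, being
the quantity comparable to published tendon failure stresses. Strain is
stress over an elastic modulus of 819 MPa (mean of published human AT
material tests), the length change is strain times the resting tendon
length, and the stored energy is the Hookean `0.5 F ΔL` discounted by a
resilience of 0.93. Both constants are configurable
(`tendon_constants()`). Viscoelasticity and strain-dependent CSA are out
of scope.

## Statistics

Hypothesis tests are directional by design: the spring hypothesis predicts
a *positive* SNW–moment-arm correlation and *negative* correlations of
mass-specific stress and energy with the moment arm, so one-tailed Pearson
tests with a priori directions are used. Correlations are computed at step
level by default (each step one observation, as the source analyses print
step-level degrees of freedom); a subject-mean option is provided because
step-level pooling ignores within-subject clustering.

The mixed model is a subject-random-intercept linear model fitted by
maximum likelihood on z-scored response and predictors, so coefficients
are standardized beta-weights. Inference uses Wald z-tests; reproducing
any particular package's denominator degrees of freedom is a non-goal.
The fit itself is delegated to `lme4::lmer()`; the module contributes the
z-scoring, the collinearity diagnostics and the standardized reporting
surface, and is cross-checked against `nlme::lme` in the tests.

## The synthetic gait generator

The generator emulates a recreationally fit adult cohort crossing
floor-mounted force plates barefoot at five self-selected speeds. Default
conditions: 24 subjects, body mass 64.15 ± 9.84 kg, AT moment arm
4.27 ± 0.48 cm truncated to 3.12–5.01 cm and correlated with mass
(target r ≈ 0.62), kinematics at 500 Hz, force at 1 kHz, marker noise
1 mm SD, force noise 2 N SD. Froude-number targets per gait (walk 0.130,
fast walk 0.245, jog 0.362, run 0.662, sprint 1.086, jittered with the
matching SDs truncated at ±1.2 SD) set the progression speed; stance
durations run from 0.65 s (walk) to 0.19 s (sprint). Vertical GRF is a
sum of raised-cosine lobes — two (≈1.1 × body weight) for walking gaits,
one (2.2–2.8 × BW) for running gaits — windowed to vanish exactly at
touchdown and toe-off; the fore-aft force is a braking-then-propulsive
sinusoid with zero net impulse; the COP travels monotonically heel to
toe.

Kinematics are prescribed forward: a metatarsal-anchored foot whose heel
rises by a per-gait push-off pitch late in stance, a hip progressing at
the Froude-consistent speed with an upward (walking) or downward
(running) mid-stance bounce, and the knee placed by two-link inverse
kinematics. Every shape is C¹-smooth so finite differences behave. The
per-gait push-off pitch and bounce were chosen once so that the ankle SNW
means fall in the published per-gait pattern (lowest when jogging,
highest when sprinting); they are configuration, not claims.

**Ground truth.** Net joint moments, ankle muscle force and stored tendon
energy are computed *forward* from the noise-free series by an independent
transcription of the same free-body equations the pipeline inverts. This
"shared-equation oracle" is deliberate: on noise-free input, processed
without filtering, the inverse pipeline must reproduce the forward
construction to 1e-6 relative — any discrepancy is an implementation
defect, not modelling error. Measurement noise is added only to the
recorded trial, never to the truth channel.

**Effect injection.** With `effect_injection = TRUE` (default), the
moment-arm → load mechanism is present mechanically: muscle force follows
`F = M / r` with per-subject ankle arms, so shorter-heeled subjects carry
larger mass-specific tendon stress and store more energy; in addition,
shorter-heeled subjects push off less steeply at run and sprint, giving
them more spring-like (lower) ankle SNW. With
`effect_injection = FALSE`, the COP lever is rescaled by each subject's
arm (making moments proportional to `r`, so forces are independent of
heel length) and the moment arm is drawn independently of all other
traits — without that decoupling, mass-specific stress (∝ 1/mass under
the default allometry) would correlate with the arm purely through the
arm–mass correlation and masquerade as an effect.

**What the generator does not emulate.** Soft-tissue artefact, marker
dropout, force-plate targeting failures, left/right asymmetry, trunk
motion (the hip angle is measured against an assumed-vertical trunk),
foot-strike-pattern diversity (all trials are heel-start; a forefoot COP
profile interacts with the push-off channel and is not modelled), and
genuinely measured tendon material properties. Peak sprint tendon
stresses in the synthetic cohort (~60 MPa) are consequently lower than
the ~110 MPa reported from real sprint data. Passing recovery tests on
this generator therefore demonstrates the correctness and sensitivity of
the *pipeline*, not the field validity of the waveform family.

## Numerical choices and degenerate inputs

* Integration is the composite trapezoid rule throughout.
* Stance windows are half-open frame intervals `[start, end)`; intervals
  shorter than the minimum duration are discarded.
* A COP more than 5 cm outside the heel–toe marker span triggers a
  warning (registration problem), not an error.
* Zero-length marker segments, non-positive moment arms, zero ankle force
  impulses and all-zero work decompositions raise errors naming the frame
  or field; undefined-SNW steps are flagged and excluded rather than
  silently dropped.
* Random streams derive from one master seed via per-subject/per-trial
  counters, so cohorts are bit-identical under a fixed seed regardless of
  generation order.

## Problem sizes used in the test-suite and acceptance runs

Unit and property tests use cohorts of 2–12 subjects with 1–3 steps per
gait; the recovery checks use the full default conditions (24 subjects,
run + sprint, 3 steps per gait) across five seeds, and the mixed-model
recovery uses 50 subjects × 10 steps. The acceptance script regenerates
the complete 24-subject × 5-gait × 3-step cohort (360 trials) from the
given seed and recomputes every reported statistic from scratch.
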