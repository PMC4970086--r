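---
title: "Methods: autonomous quality control of IMU joint-orientation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomous quality control of IMU joint-orientation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Joint angles measured with pairs of body-worn inertial modules (AHRS: an
IMU plus a sensor-fusion filter that outputs 3D orientation in a shared
gravity/magnetic-north frame) are attractive for clinical mobility
assessment because they need no laboratory. Their weakness is that accuracy
is not constant: a persistent difference in the magnetic environment around
the two modules of a joint erodes their shared heading reference, and
angular velocity beyond the fusion filter's comfortable operating range
degrades tracking. In remote monitoring nobody can check each recording
against a gold standard, so the practical question is not "how do we make
every measurement accurate" but "can we tell, from the raw signals alone,
which segments to trust".

`imuqc` implements an autonomous quality-control (QC) pipeline built around
that question. A segment of joint-orientation data (one task phase, one
joint) is summarized by sixteen features of the raw accelerometer,
gyroscope and magnetometer streams of the two modules spanning the joint,
and a small feedforward neural network classifies the segment as
acceptable or not. Accuracy ground truth, used only for training labels
and evaluation, is the root-mean-squared difference (RMSD) of the joint's
global motion angle against a reference system: segments with RMSD at most
5 degrees are *good* (within accepted error bounds for clinical
kinematics), above 10 degrees *bad*, in between *tolerable*. Both
boundaries belong to the lower category. The classifier's target is the
binary accept decision (accept = good); *sensitivity* is the fraction of
good segments accepted and *specificity* the fraction of bad segments
rejected, with tolerable segments entering neither metric.

## Orientation representation and the accuracy measure

All orientations are unit quaternions, scalar-first `(w, x, y, z)` with the
Hamilton product; the field uses both scalar-first and scalar-last
conventions, so every I/O format documents this choice. Joint orientation
is `conj(q_prox) * q_dist`, re-expressed against the first sample of a
segment so any constant mounting offset cancels. The *global motion angle*
`theta(t) = 2 acos(|w(t)|)` is the total rotation away from the initial
configuration regardless of axis. It is deliberately plane-agnostic: it
measures the technology (can the two modules agree on how far the joint
moved?) without entangling sensor accuracy with body-calibration and
biomechanical-model errors. RMSD between the AHRS-derived and reference
angle series over a segment is the accuracy measure; whether RMSD should
instead be taken on the full 3-DoF orientation difference is a genuine
design fork, and the global-motion reading was adopted because accuracy is
defined here as agreement on the change in global joint motion.

Two numerical details matter. Unit quaternions double-cover rotations, so
consecutive samples are forced onto the same hemisphere (flip `q -> -q`
when the running dot product goes negative) before any interpolation or
angle extraction; otherwise `theta(t)` shows spurious 360-degree jumps.
And the `acos` argument is clamped to `[0, 1]` because renormalized
products overshoot unity by a few ulp.

## Signal preparation

Raw streams arrive at 60 Hz and are linearly interpolated onto a 100 Hz
grid (the reference system's rate) before comparison; quaternion series are
interpolated component-wise after continuity enforcement and renormalized,
which is indistinguishable from spherical interpolation at the small
inter-sample rotations of human movement at 60 Hz. The interpolation
scheme is recorded here as a choice, not a given: linear was chosen for
transparency, and its error on band-limited human movement (worst case
`h^2/8 * max|f''|`) is far below the 5-degree decision boundary.

The reference and AHRS clocks are aligned by maximizing the normalized
cross-correlation over integer lags, tie-breaking toward the smallest
magnitude. The correlation signal is the *first difference* of the global
motion angle of the most mobile joint (highest angular-velocity variance):
differencing removes slow heading drift from the AHRS estimate, which
otherwise biases the correlation of the raw angle ramp — in development
measurements the raw-angle alignment was off by up to 10 samples while the
differenced alignment stayed within 2. Sub-sample refinement is not
attempted; the QC features are segment averages and insensitive to
sub-sample offsets. Task segmentation is consumed from an annotation table
(0-based, half-open sample indices); automatic segmentation is a separate
problem and out of scope.

## The sixteen features

Per joint-segment, from the two modules' raw streams (module 1 = proximal,
module 2 = distal):

| # | Feature | Why |
|---|---------|-----|
| 1-2 | mean of the magnetometer-norm deviation from a reference value, per module | is the local field perturbed at all? |
| 3-4 | population variance of the magnetometer norm, per module | is the environment stable across the segment? |
| 5-6 | mean acceleration norm (g), per module | motion intensity; 1 g at rest |
| 7-8 | mean angular-velocity norm (deg/s), per module | velocity is a known accuracy driver |
| 9-14 | per-axis proportions of mean absolute angular velocity (3 per module) | direction of motion, a proxy the classifier can use without knowing the task |
| 15 | difference of the two modules' mean magnetometer norms | do the modules share an inertial reference? |
| 16 | the same difference in the *previous* sequence | recent magnetic history keeps acting on the fusion filter |

The "magnetic field" of a module is summarized by the Euclidean norm of
the 3-axis magnetometer: the norm is invariant to module orientation, so
it characterizes the environment rather than the motion. The reference
magnitude is a configuration scalar (`mag_reference`, default 1 in
normalized field units) representing the calibration-time field; whether
it should be global or per-participant is left to the caller. Axis
proportions always sum to one per module; a segment with no rotation at
all carries no direction information and falls back to `(1/3, 1/3, 1/3)`.
For the first phase of a trial there is no previous sequence, so f16
reuses f15 and the row is flagged. Acceleration is used gravity-included
(no subtraction): the classifier is meant to see the module's raw
operating conditions. Variance is the population variance (divide by N).

Features are compressed with a *signed* square root,
`sign(x) * sqrt(|x|)` — the plain square root the transform is based on is
undefined for the signed field-difference features 1, 2, 15, 16 — then
expressed as z-scores with mean and standard deviation estimated on the
training partition only, and clipped to ±3 SD in a single pass (outliers
are brought back to the limit, not removed). The normalization statistics
persist with the trained network and are applied unchanged to validation
data.

## The classifier

A feedforward network with 16 inputs, a single hidden layer of six tanh
neurons and one tanh output: small enough not to overfit a few thousand
training segments, complex enough to capture feature interactions. The
accept decision is `score > 0`, with an exact zero rejected
(conservative). Training minimizes

```
sum_i gain(class_i) * (score_i - target_i)^2 + lambda * ||W||^2
```

with `target = +1` for good and `-1` for tolerable/bad segments. The
per-class error gains default to `N_total / (K * N_class)` over the K
quality categories present, so the scarce bad segments are not drowned out
by the plentiful good ones — the decision is binary but the balancing
respects all three categories. The L2 penalty (`lambda`, default `1e-3`,
biases unpenalized) plays the role of the prior in Bayesian-regularized
backpropagation; full evidence-framework re-estimation of `lambda` is out
of scope, but a small grid with selection on an internal stratified
held-out fold is available when a vector of candidates is supplied.

Gradients are obtained by backpropagation and minimized, by default, with
BFGS (`stats::optim`) in full batch — the problem has ~115 parameters and
a few thousand examples, so batch quasi-Newton is fast and deterministic.
The loss is non-convex and a single unlucky initialization can stall on a
plateau, so training restarts from three seeded initializations (uniform
on ±0.5) and keeps the lowest penalized loss; everything is reproducible
bit-for-bit given the configuration seed. A plain fixed-step
gradient-descent mode exists as well, mainly because its monotone loss
decrease under a small learning rate is a useful correctness check.

## The synthetic cohort generator

There is no deposited recording, so the package ships a generator that
emulates the study design end to end: 20 participants, each performing a
5 m timed-up-and-go 9 times (3 speed conditions × 3 repetitions), split
into 6 phases (sit, sit-to-stand, walk, walk, turn, turn-to-sit), with 4
joints (trunk, hip, knee, ankle) tracked by 5 body-segment modules (torso,
pelvis, thigh, shank, foot), raw signals at 60 Hz. Defaults *are* those
study conditions; `cohort_config()` exposes them.

Each module gets a smooth body angular-velocity profile per phase:
near-still sitting (postural sway of a few deg/s), a half-sine-squared
sit-to-stand pulse (hip/knee excursion 65-70 degrees over 1.5 s at natural
speed), sinusoidal walking with per-module amplitudes growing distally
(torso 4 to foot 60 degrees) and cadence 0.9 Hz scaled by the speed
condition {0.7, 1.0, 1.4} (durations divide by the same factor), a
180-degree heading pulse for turning, and a combined reverse pulse for
turn-to-sit. Participant heterogeneity enters as seeded uniform scale
factors on amplitude (±15%) and cadence (±10%). True orientation is the
midpoint integration of the body rates — by construction, so the
"gyro integrates to the truth" invariant is testable against an
independent integrator. Raw signals derive from the same kinematics:
gyro = rates + Gaussian noise (1 deg/s); accel = rotated gravity + a
motion-scaled dynamic component + noise (0.02 g), norm 1 g at rest;
magnetometer = the rotated world field + noise (0.01).

The magnetic disturbance emulates a floor-level source: field norms are
scaled by `1 + a * exp(-h/0.3 m) * loc(phase)`, with module height `h`
(foot 0.05 m ... torso 1.3 m), per-trial amplitude `a ~ U(0, 1.5)`, and a
location factor largest around the chair (sit and transfer phases) and
smaller along the walkway. The laboratory's actual disturbance field is
unknown and unknowable from the study, so these presets were calibrated
once, by construction, to reproduce the qualitative ordering of the
original data — trunk cleanest, ankle worst, all three quality categories
represented — and then frozen; a `severe_amplitude` preset (2.5) is
guaranteed to push a sitting ankle segment past the bad threshold.

AHRS estimates are the truth composed with a heading-axis (vertical) error
— heading is the axis the magnetometer constrains — whose drift rate is

```
base + jitter * (drift_gain * disturbance + vel_gain * max(0, |gyro| - omega0))
```

accumulated over the trial, plus white orientation noise (0.3 degrees).
`drift_gain` is 8 deg/s per unit relative field disturbance and
`vel_gain` 0.1 deg/s per deg/s of excess speed; `omega0 = 180` deg/s was
chosen during calibration so that only genuinely fast distal-segment
motion (fast-condition shank and foot) triggers velocity-driven drift —
the literature says accuracy degrades "above a certain level" without
quantifying it. The per-trial, per-module log-normal jitter (sdlog 0.3)
stands in for disturbance geometry the norm-based features cannot see, and
the small half-normal baseline drift (0.4 deg/s) represents residual
fusion error present even in clean conditions. The commercial fusion
filter itself is deliberately *not* simulated: the QC method treats the
AHRS as a black box, and the parametric error model encodes exactly the
accuracy drivers the classifier is supposed to recognize, which keeps the
good/bad structure both controllable and learnable.

What the generator does **not** emulate — and hence what passing tests do
not certify about real recordings: soft-tissue artefact, sensor bias and
scale-factor miscalibration, transient (as opposed to persistent) magnetic
events, fusion-filter adaptation dynamics, pathological gait, and
disturbance-geometry effects beyond a scalar norm. Results on synthetic
cohorts demonstrate that the pipeline is implemented correctly and that
the feature set can carry the accuracy signal; they are not a clinical
validation.

## The evaluation pipeline

`run_pipeline()` chains preparation, segmentation, feature extraction,
labeling, normalization (fitted on the training half only), training,
held-out prediction, and reporting. The participant split is always at
participant level — a segment-level split would leak participant
idiosyncrasies into validation — with a seeded shuffle, half and half, and
an explicit check that no participant appears in both partitions. The
report gives sensitivity and specificity per partition plus a per-(task,
joint) table of segment counts and mean (SD) RMSD before and after
discarding rejected segments, with the two walking phases pooled into one
row. On default synthetic cohorts the held-out sensitivity and specificity
both clear 0.83, the suite's acceptance bar; `scripts/acceptance.R`
recomputes this from scratch.

Problem sizes: the shipped configuration (20 participants, 4320 segments,
~15 s of 60 Hz data per trial across 5 modules) runs the whole pipeline in
about a minute on one core; unit tests use 1-2 participant cohorts. These
sizes were chosen as the smallest at which the cohort-level statistics
(label mix per joint, held-out metrics) are stable.

## Known limitations

- The error model is heading-only; real fusion errors have inclination
  components that global motion angle partly hides.
- Feature 16's first-phase fallback (reuse f15) slightly blurs the
  temporal information for sitting segments.
- The network's decision threshold is fixed at 0; applications wanting a
  different sensitivity/specificity trade-off must retrain with different
  gains rather than move the threshold (scores saturate near ±1, so
  threshold-shifting is ineffective).
- Integer-lag synchronization leaves sub-sample residuals that add a small
  RMSD floor to the fastest segments.
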