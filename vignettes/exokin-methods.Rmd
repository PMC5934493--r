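---
title: "Predicting human joint angles from exoskeleton motion: models and methods"
author: "exokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting human joint angles from exoskeleton motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exokin)
```

## The problem

A lower-limb exoskeleton is strapped to the wearer's pelvis, shank and
foot, but the limb and the device never move identically: the device's
joint axes sit centimetres away from the anatomical axes, belts and soft
tissue comply, and the extensible links rarely match the wearer's segment
lengths exactly. Most control and assessment work nonetheless assumes the
*rigid* approximation — human joint angles equal exoskeleton joint
angles. This package implements a subject-specific alternative (EIKPE,
extended inverse-kinematics posture estimation): model the limb and the
device as one parallel kinematic chain closed by the physical fixations,
and for each frame solve the human hip, knee and ankle flexion angles
that best satisfy those closure constraints given the known exoskeleton
angles. Everything needed to exercise the method — skeletal scaling,
device-model adjustment, marker-based ground truth, a seeded synthetic
gait generator, and the evaluation metrics — is included, so the full
study runs with no external data.

## Kinematic conventions

Segments are rigid bodies with the origin at the proximal joint, +Y
pointing proximally (segments hang along −Y), +X anterior and +Z to the
subject's right. All modelled joints rotate about +Z (sagittal plane),
positive by the right-hand rule, which makes hip, knee and ankle flexion
positive for the right leg; a joint is neutral (0°) when the Y axes of
its two segments are parallel. Angles are handled in degrees at every
interface (radians appear only inside trigonometric calls); angles are
reported in (−180°, 180°] with ties resolved to +180°. The free 6-DOF
base joint orders its coordinates `(tx, ty, tz, rx, ry, rz)` with
intrinsic XYZ Euler rotations. Note that several anatomical conventions
(e.g. knee flexion measured negative in some musculoskeletal software)
differ by a sign; comparisons with such outputs need a sign flip.

## The models

**Human.** `build_generic_human()` builds a right lower limb: ground →
pelvis (free 6-DOF), then hip, knee and ankle sagittal revolutes with
default segment lengths (pelvis 0.20, femur 0.40, tibia 0.38, foot
0.25 m — round mid-range adult values, all overridable). Hip
ab-adduction and axial rotation enter forward kinematics as frozen
constants held at their static-posture values: the device has no hip
ab-adduction or rotation degrees of freedom, so during exoskeleton gait
these angles stay close to their standing values, and only the three
sagittal angles are estimable. Twelve markers follow a standard gait
protocol (heel, first/fifth metatarsal, malleolus, shank cluster,
lateral knee, thigh cluster, trochanter). Only Mk0–Mk3, Mk7, Mk11 have
protocol-fixed identities; the cluster layout is this package's choice.

A deliberate feature of the layout is that landmarks do *not* coincide
with joint axes: by default the trochanter marker sits 55 mm above the
hip center, the lateral knee marker 10 mm below the knee axis. Because
the device is fitted (and the device *model* is adjusted) to marker
heights, these offsets are exactly the human–device axis misalignment
that makes the rigid assumption fail; setting them to zero produces an
idealized subject whose device axes coincide with the joints.

**Exoskeleton.** `build_exo_model()`: corset (root), thigh link, shank
link and sole, three parallel-axis sagittal revolutes, adjustable link
lengths, and five markers (hip/knee/ankle motor centers, thigh/shank bar
midpoints). There is no marker on the sole — which matters below.

**Scaling.** `compute_scale_factors()` divides measured by model
marker-pair distances (femur: Mk11–Mk7; tibia: Mk7–Mk3; foot: Mk2–Mk1)
on the static trial without the exoskeleton, and `apply_scaling()`
stretches lengths, longitudinal marker offsets and distal joint
attachments along each segment's Y axis; a per-segment manual override
(a config entry standing in for the visual-inspection step of practical
workflows) takes precedence. With the marker pairs on the segment axes
the recovery of generating factors is exact at the neutral static pose;
with non-zero axis offsets the tibia pair crosses the knee and recovery
is exact only to the extent the marker offsets scale with the segment —
a protocol approximation worth knowing about.

**Coupling.** `assemble_coupled()` welds the pelvis into the corset:
hip centers aligned along the anterior–posterior axis, and the device
hip axis placed at the Mk11 height (the same marker-height rule used for
the links, so the whole device model is registered to the landmarks).
The worn static capture then calibrates the static posture: a marker IK
solve for hip flexion/ab-adduction/rotation, knee, ankle and the device
hip/knee angles, after which ab-adduction and rotation are frozen. A
static residual RMS above 1 cm sets a `poor_initialization` flag (with
a warning) rather than failing — the automated analogue of "inspect and
revise manually".

Two deliberate reference conventions resolve quantities this marker set
cannot observe:

* **Base orientation.** With no pelvis or corset cluster, rotating the
  whole assembly about the shared hip axis while counter-rotating both
  hip angles changes no marker position — an exact gauge freedom. Base
  rotations therefore stay at the registered capture orientation and
  only base translations are estimated (from the static frame; walking
  trials re-estimate them on the first frame and hold them, the
  treadmill volume being fixed). A worn-corset tilt consequently appears
  as a common constant in the hip and exo-hip channels of ground truth,
  baseline and estimate alike, and cancels in every comparison.
* **Exoskeleton ankle reference.** With no sole marker the static device
  ankle angle is unobservable; it is referenced to zero, and the
  constraint anchors and all estimated exo-ankle series share that
  reference, so the closure remains consistent. The unidentified
  constant is the familiar static-calibration bias of this protocol.

## The fixation constraints

`make_default_constraint_set()` expresses the physical attachments as
11 residual equations:

* pelvis–corset: a rigid 6-DOF junction, implemented structurally (the
  two bodies share one tree), hence no residual rows;
* tibia brace: a point-on-line constraint (2 residuals) between a
  mid-shank point and the shank-bar axis, the basis vectors completing
  the line direction fixed once at construction so residual components
  stay continuous over the gait cycle;
* foot straps: three point-to-point constraints (9 residuals) at heel,
  first- and fifth-metatarsal sole positions.

Exoskeleton-side anchors are the images of the human-side anchor points
at the calibrated static posture, so every residual is exactly zero
there; anchor positions are overridable because the true brace contact
points are device-specific.

## The estimator

`eikpe()` fixes the exoskeleton coordinates to their known values frame
by frame and minimizes the squared residual norm over the three human
flexion angles (11 equations, 3 unknowns, unweighted) by damped
least squares (`minpack.lm::nls.lm`, numerical Jacobian, up to 100
iterations, `ftol` 1e-15). Frames warm-start from the previous solution
(frame 1 from the static posture) for speed and branch continuity. Two
numerical safeguards matter in practice:

* warm-start values below 1e-9 are snapped to zero — the underlying
  `lmdif` scales finite-difference steps with the parameter magnitude,
  and a start of 1e-30 would freeze that coordinate;
* if the converged residual exceeds the residual at the rigid
  configuration (human = exoskeleton angles), the solve is repeated from
  the rigid start and the better solution kept. Levenberg–Marquardt is
  monotone from its start, so the returned residual provably never
  exceeds the rigid baseline's.

The rigid baseline itself is `rigid_estimate()`: the identity map.

`marker_ik()` (ground truth) minimizes weighted squared marker distances
over any chosen subset of coordinates with the same machinery, drops
`NaN` (occluded) markers per frame, errors on frames with fewer than
three usable markers, and adds a deterministic basin rescue: if a
frame's residual RMS exceeds 1 cm the solve is retried from a coarse
grid (quartiles of each revolute's limits), which protects the first
frame of a trial that starts far from neutral (the default gait profile
begins at peak knee flexion). The exoskeleton ankle is computed
separately by `exo_ankle_from_markers()`: the rotation, in the exo shank
frame, of the line from the malleolus marker to the virtual mid-foot
marker Mk14 (midpoint of Mk0 and Mk1, added by
`add_virtual_midpoint_marker()`) relative to the static posture. A naive
position-matching solve would instead let the short-lever ankle absorb
proximal position discrepancies with large angle excursions.

## The synthetic study conditions

`make_synthetic_subject()` generates everything a trial needs. The gait
profile is a two-harmonic Fourier series per joint at cadence 0.5
strides/s (slow treadmill walking, ~1 km/h), 100 Hz, 10 s by default,
with coefficients chosen to produce slow-gait ranges (hip −10…25°, knee
0…60°, ankle −15…10°). Subject scale factors default to uniform draws in
0.9–1.1. The static posture is neutral upright standing.

Exoskeleton motion is produced in one of two ways:

* **closure (study conditions):** the true worn device — links set to
  the marker-height differences plus a small extensible-plate error,
  corset welded with a worn shift/tilt — follows the limb by per-frame
  least-squares closure of its own fixation constraints, plus smooth
  band-limited compliance noise (white noise convolved with a ~0.15 s
  Gaussian kernel, rescaled). This is the physically consistent regime:
  the foot cannot leave the sole it is strapped to, and the relative
  motion the rigid baseline suffers emerges from the axis-offset
  geometry.
* **affine surrogate (`derive_exo_motion()`):** per-joint
  `gain · v_H(t − lag) + offset + smooth noise`, lags applied as
  periodic shifts. It is convenient for unit-level tests (its effects
  are exactly predictable channel-wise) but deliberately *not* the study
  default: independently distorted joint angles violate the closure
  constraints by centimetres, a regime in which no constraint-based
  estimator should be expected to help.

The `"misaligned"` preset holds the study conditions: default axis
offsets, corset worn 3 mm anterior / 2 mm low with 0.5° tilt, link
errors +2/−1.5 mm, compliance noise 0.3°, marker noise 1 mm. The
`"none"` preset (with zero axis offsets) gives the idealized
perfect-alignment world used by the identity checks. Markers are
synthesized by forward kinematics of the true coupled model with seeded
Gaussian noise; every random draw flows from an explicit seed, and
fixed seeds reproduce outputs bitwise. The worn static trial keeps all
twelve human markers (captured before the knee and trochanter markers
are removed for walking); walking trials carry ten human markers plus
the five device markers.

What the generator does **not** emulate: genuine soft-tissue
deformation and marker wobble (markers are rigid on their segments up to
isotropic noise), pelvis motion during treadmill walking (the base is
stationary), left-limb and torso kinematics, ground contact and forces,
and any time-varying strap compliance beyond the smooth noise term.
Passing tests therefore demonstrate the estimator's correctness and its
advantage under geometric misalignment — not robustness to every
artifact of real captures.

## Evaluation

`rmse()` and `rome()` implement the two accuracy metrics: root mean
squared error, and the range-of-motion error `(max x − min x) −
(max y − min y)` with `x` the ground-truth series. ROME is kept signed
per trial and aggregated as a magnitude in reports — amplitude errors in
either direction are errors. `improvement_pct()` is the error reduction
`100 (e_rigid − e_eikpe) / e_rigid`, computed from unrounded mean errors
and rounded only for display. `ranksum_test()` is a two-sided
Wilcoxon–Mann–Whitney test, exact by full enumeration of rank
assignments (mid-ranks, so valid under ties) up to a combined sample
size of 16 — comfortably covering 7-vs-7 — with a tie-corrected,
continuity-corrected normal approximation beyond; a rank-sum test is
used (rather than the paired signed-rank variant) because the two
methods' per-subject error samples are compared as two populations, with
no multiple-testing correction across the six joint/metric cells.
`build_report()` assembles the per-subject errors into the standard
table (mean ± sd per joint, metric and method, improvement, p-value) and
`plot()` draws the box plots.

## Problem sizes

The bundled tests and the acceptance script size the simulations as
follows, as the package's own choices: identity and ground-truth
round-trip checks use one 10 s trial at 100 Hz; the misalignment study
uses 4 s trials (two full strides), ten seeds for the robustness check
and seven subjects for the reported study; the grid-search oracle checks
20 frames at a 0.01° final grid. Longer trials change none of the
qualitative conclusions, only runtimes.

## Known limitations

* The three estimable DOFs assume a sagittal device; out-of-plane
  estimation would need a richer constraint set and marker protocol.
* Constraint anchors are constant over time; compliant, load-dependent
  attachments are outside the model (and are the main reason real
  estimates will be worse than the synthetic floor here).
* The static-calibration references (base orientation, exo ankle) leave
  constant biases unidentified; all comparisons inside the package are
  consistent under them, but absolute angles exported elsewhere inherit
  them.
* Scaling is marker-pair based along segment axes only: no account of
  bone geometry deviations, and only the right limb is personalized.
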