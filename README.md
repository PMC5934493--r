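# exokin

Subject-specific prediction of human lower-limb joint angles from the
joint angles of a worn exoskeleton.

## The problem

A lower-limb exoskeleton and the limb it is strapped to never move
identically: the device's joint axes sit centimetres from the anatomical
axes (the trochanter is well above the hip center; braces ride on soft
tissue), link lengths only approximately match the wearer, and belts
comply. The common *rigid* assumption — human angles equal exoskeleton
angles — therefore mis-estimates the wearer's kinematics, worst at the
knee. `exokin` implements the constraint-closure alternative: a scaled,
subject-specific skeletal model of the right leg is coupled to a
kinematic model of the device through its physical fixations

* a rigid pelvis–corset junction (structural weld),
* a point-on-line constraint between a mid-shank point and the shank
  bar (2 residuals),
* three point-to-point constraints between foot and sole (9 residuals),

and for every frame the human hip, knee and ankle flexion angles
`ṽ_H(t)` are obtained from the known exoskeleton angles `v_R(t)` by
damped-least-squares closure of the 11 constraint equations:

    ṽ_H(t) = argmin_h || C(h, v_R(t)) ||²

Accuracy against marker-based ground truth is summarized by
`RMSE = sqrt(mean((x − y)²))` and the range-of-motion error
`ROME = (max x − min x) − (max y − min y)`, with error reduction
`100·(e_rigid − e_eikpe)/e_rigid` and exact two-sided
Wilcoxon–Mann–Whitney tests across subjects.

The package contains the full study apparatus: generic model +
marker-pair scaling, exoskeleton link adjustment and pelvis–corset
assembly from static captures, marker inverse kinematics (TRC files) for
ground truth, the estimator and the rigid baseline, evaluation reports,
and a fully seeded synthetic gait generator (12 human + 5 device
markers, treadmill walking at 100 Hz) so everything runs with no
external data. See `vignette("exokin-methods")` for the modelling
details.

## Worked example

Simulate one subject under the misaligned study conditions, run the
pipeline (scaling → assembly → ground-truth IK → both estimators), and
compare:

```r
library(exokin)

subj <- make_synthetic_subject(
  seed = 42, soft = soft_tissue_preset("misaligned", seed = 42),
  duration = 4)
res <- process_subject(subj)

fit <- res$eikpe_fit
print(fit)
#> EIKPE constraint-closure estimate
#> 400 frames; 400 converged; constraint residual RMS mean 0.00199 m (rigid baseline 0.00554 m)

round(sapply(names(res$v_H_gt$channels), function(ch) c(
  rigid = rmse(res$v_H_gt$channels[[ch]], res$rigid$channels[[ch]]),
  eikpe = rmse(res$v_H_gt$channels[[ch]], res$eikpe$channels[[ch]]))), 2)
#>       hip_flexion knee_flexion ankle_flexion
#> rigid        1.70         2.56          1.37
#> eikpe        0.35         0.48          0.85
```

The rigid baseline errs most at the knee (2.6° RMSE), where the
human–device axis misalignment is largest; the constraint-closure
estimate cuts every joint's error (here by 38–81%). A multi-subject
study with the standard table layout:

```r
study <- run_pipeline(pipeline_config(n_subjects = 7, duration = 4,
                                      preset = "misaligned", seed = 1))
print(study$report)
#> joint angle estimation errors (7 subjects, mean ± sd, degrees)
#>
#>  joint metric     rigid     eikpe improvement     p
#>    hip   RMSE 1.6 ± 0.1 0.4 ± 0.1         72% 0.001
#>    hip   ROME 3.3 ± 0.1 0.5 ± 0.2         84% 0.001
#>   knee   RMSE 2.5 ± 0.2 0.5 ± 0.1         78% 0.001
#>   knee   ROME 5.2 ± 0.8 0.6 ± 0.4         89% 0.001
#>  ankle   RMSE 1.3 ± 0.2 0.8 ± 0.1         37% 0.001
#>  ankle   ROME 0.5 ± 0.3 1.8 ± 0.7       -237% 0.001
```

Each row gives the mean ± sd error (|ROME| for the amplitude metric)
across subjects for the rigid baseline and the closure estimate, the
percentage error reduction, and the exact rank-sum p-value comparing the
two methods' per-subject errors. Under these synthetic conditions the
closure estimate wins decisively on shape everywhere and on amplitude at
hip and knee; the negative ankle-ROME cell shows the estimate slightly
over-shooting the ankle's (already well-matched, 0.5°) amplitude — the
end of the chain accumulates the residual geometry error. A command-line
wrapper for the same pipeline is installed at `inst/cli/exokin.R`
(`simulate`, `run-all`, `evaluate`).

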