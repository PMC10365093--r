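# headmotion

Quantification of rigid-body head motion during MRI examinations, from
pose streams recorded by markerless tracking devices.

Head motion is a leading cause of artefacts in structural MRI, and it is
most severe in paediatric imaging: young children either move in the
scanner or are examined under general anaesthesia (GA). To understand
*how* patients move — and to compare motion between anaesthetised and
awake cohorts — the head's pose can be tracked continuously (~30 Hz) as
a stream of rigid-body transforms. This package turns such pose streams
into interpretable motion metrics and cohort-level statistics:

* **Rigid-transform algebra** — composition, inversion, frame
  conjugation with a cross-calibration transform (tracker → scanner
  RAS), and decomposition of each pose `T_t = (R_t, t_t)` into six
  motion parameters: translations `(t_x, t_y, t_z)` in mm and
  Tait–Bryan angles `(r_x, r_y, r_z)` in degrees for the factorization
  `R = R_z(r_z) R_y(r_y) R_x(r_x)`.
* **Displacement metrics** — poses are masked to the MR acquisition
  windows of a scan schedule and re-referenced to the pose at the
  temporal midpoint of the structural (MPRAGE) sequence, the acquisition
  of the centre of k-space. For a tracked point `p` the displacement is
  `d(t) = ‖R_t p + t_t − p‖` (mm), summarized per patient as mean,
  median and maximum displacement, and **motion-free time**: the
  fraction of scan time with `d(t) < 2 mm`.
* **Region kinematics** — the same transforms applied to brain-region
  centroids (16 bilateral cortical/subcortical regions) give per-region,
  per-axis displacement summaries.
* **Cohort statistics** — Mann–Whitney U tests (exact null for small
  samples, tie-corrected normal approximation otherwise) with
  Benjamini–Hochberg FDR control per comparison family, plus the
  `median ± SD` cohort summary style appropriate for skewed metrics.
* **Synthetic motion generator** — drift (slow translation along −z,
  out of the bore), nodding rotation pulses about x, brief displacement
  spikes and AR(1) jitter, with separable anaesthetised/awake profiles
  and full ground truth, used to validate every downstream stage.

## Worked example

```r
library(headmotion)

sch <- default_schedule()                     # 5 MR windows, MPRAGE first
sim <- simulate_trace(awake_profile(seed = 7), sch, rate_hz = 5)
fit <- patient_motion(sim$trace, sch, keep_series = TRUE)
summary(fit)
#> Head-motion analysis: 4995 MR samples, reference at 133.0 s
#> Motion metrics (centroid): mean 1.379 / median 1.479 / max 3.341 mm; motion-free 71.5% (< 2 mm)
#>
#> Per-axis components (mean over time):
#>      channel axis   mean_abs mean_signed
#>  translation    x 0.04644278 -0.02471688
#>  translation    y 0.09631901  0.09133827
#>  translation    z 1.31412989 -1.26175712
#>     rotation    x 0.05410198 -0.03196135
#>     rotation    y 0.04952594  0.04799287
#>     rotation    z 0.03272374 -0.02651606
```

This simulated awake patient drifts out of the scanner: the z
translation dominates every other component (1.31 mm mean absolute) and
its signed mean is negative, while displacement exceeds the 2 mm
threshold during ~28% of MR acquisition time.

Cohort level — 18 anaesthetised vs 43 awake synthetic patients:

```r
co <- make_cohort(n_ga = 18, n_awake = 43, master_seed = 1, rate_hz = 5)
cm <- cohort_motion(co)
cm
#> Cohort motion tables: 61 patients (awake n=43, GA n=18)
#>   GA mean displacement: 0.45 ± 0.18 mm (median ± SD)
#>   awake mean displacement: 1.45 ± 0.53 mm (median ± SD)

cohort_comparisons(cm$metrics, cm$axes)
```

All four displacement metrics separate the groups after FDR correction
(p ≈ 1e-8 and below at these effect sizes); within both groups the
absolute z translation exceeds x and y, and only the awake group shows
significant excess nodding (|r_x| > |r_y|, |r_z|).

A command-line interface wrapping the same functions ships at
`inst/cli/headmotion` (subcommands `simulate`, `metrics`, `decompose`,
`regions`, `compare`).

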