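---
title: "Quantifying rigid-body head motion from pose streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rigid-body head motion from pose streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headmotion)
```

## The measurement model

A markerless tracking device estimates, at roughly 30 Hz, a rigid-body
transform $T_t = (R_t, t_t)$ describing the head's pose at time $t$
relative to a device-internal reference: $R_t$ a proper rotation,
$t_t$ a translation in mm. The package treats this stream as the raw
observable and derives everything else from exact rigid algebra:

1. **Cross-calibration.** A fixed transform $C$ relates the tracker
   frame to the scanner's RAS frame (x right, y anterior, z superior —
   the axis into the bore and toward the top of the head). The same
   physical motion expressed in RAS is the conjugate
   $T'_t = C \, T_t \, C^{-1}$. Conjugation is an isometry, so every
   displacement-based metric is provably invariant under the choice of
   frame; the test suite checks this to $10^{-9}$.

2. **Masking.** Only samples acquired during MR sequence windows are
   analysed; motion during PET acquisition and dead time is discarded,
   because the clinical question concerns artefacts in the MR images.
   Windows are closed intervals from a scan schedule.

3. **Re-referencing.** All poses are expressed relative to the pose at
   the temporal midpoint of the structural (MPRAGE) window — the
   acquisition of the centre of k-space, where image quality is most
   sensitive to motion. The relative pose is
   $T_t \circ T_{\mathrm{ref}}^{-1}$: the head's motion in the fixed
   scanner frame since the reference instant. The alternative
   convention $T_{\mathrm{ref}}^{-1} \circ T_t$ (motion in head
   coordinates) was rejected because region centroids are defined in
   scanner coordinates at reference time, and displacement must be
   measured there. "Midpoint" resolves to the sample whose timestamp is
   nearest $(\mathrm{start}+\mathrm{end})/2$ of the reference window,
   ties to the earlier sample; that sample is mapped to the identity
   exactly.

4. **Displacement and metrics.** For a tracked point $p$ (the facial
   point-cloud centroid, or a brain-region centroid),
   $d(t) = \lVert R_t p + t_t - p \rVert$ in mm. Per patient the
   package reports mean, median and maximum of $d$, and the
   motion-free fraction: the fraction of scan time with
   $d(t) < \theta$, default $\theta = 2$ mm — a standard practical
   threshold for structural image quality. The inequality is strict,
   exactly as the definition is worded.

5. **Component decomposition.** Each relative transform is decomposed
   into translations along and rotations about the RAS axes. Angles are
   Tait–Bryan angles of the factorization
   $R = R_z(r_z)\,R_y(r_y)\,R_x(r_x)$, reported in degrees within
   $(-180°, 180°]$. The angle order is not canonical across devices; at
   the magnitudes relevant here (well under $2°$) all conventions agree
   to first order, and the chosen convention is recorded in every output
   header. Near gimbal lock ($|r_y| \to 90°$, unreachable for realistic
   head motion but handled anyway) the canonical solution with $r_x = 0$
   is returned and flagged. Round-tripping decompose/compose is exact to
   $10^{-9}$ over $10^4$ random small-motion transforms.

## Time weighting of motion-free time

After masking, samples are unevenly spaced: consecutive windows are
separated by minutes of untracked time. A plain sample count would be
correct only under uniform sampling, while a raw time integral would let
the masked gaps dominate. The package weights each sample by the gap to
the next sample, capped at twice the nominal sampling interval (a gap
beyond that is untracked time, not evidence of stillness or motion), and
the final sample by one nominal interval. Under uniform sampling this
reduces exactly to the sample count; both views agree in that case.
No interpolation or resampling is ever applied — metrics operate on
observed samples only.

## Cohort statistics

Displacement metrics are strongly right-skewed (confirmed by a
Kolmogorov–Smirnov check against a normal with sample mean/SD — a
conservative, Lilliefors-style usage since the parameters are
estimated), so cohorts are summarized as median ± SD and compared with
the Mann–Whitney U test, two-sided throughout. The exact permutation
null is used when $n_x n_y \le 400$ and there are no ties; otherwise
the tie-corrected normal approximation with continuity correction. The
exact branch is verified in the tests against full enumeration of all
$\binom{n_x+n_y}{n_x}$ group assignments.

Multiple testing is controlled with the Benjamini–Hochberg step-up
procedure at FDR 0.05, applied independently within each comparison
family: (i) the four displacement metrics between groups; (ii) within
each group, the per-patient mean absolute translation and rotation
components between axes; (iii) within each group and region, the
per-patient median absolute displacement between axes. Families follow
the natural reporting units of such analyses (one figure, one family);
correcting across all families jointly would mix questions of different
kinds.

Whether per-patient axis components should be means or medians over
time is a free choice; the mean is the default and the statistic is
exposed as a parameter (`axis_summaries(..., stat = "median")`).
Region-level axis summaries use the median of absolute per-axis
components, with signed medians emitted alongside for directionality.

## The synthetic motion generator

Real paediatric motion data are clinically sensitive and not
redistributable, so the package ships a generator that emulates the
reported phenomenology and provides exact ground truth. Each trace
composes four processes, in the fixed order
$T_{\mathrm{drift}} \circ T_{\mathrm{nod}} \circ T_{\mathrm{spike}}
\circ T_{\mathrm{jitter}}$ (order effects are second order at these
magnitudes):

| process | form | parameters (defaults: GA / awake) |
|---|---|---|
| drift | deterministic translation, linear or saturating (time constant 20 min) | rate mm/min along −z: 0.05 saturating / 0.08 linear |
| nodding | raised-cosine rotation pulses about x, Poisson onsets, 3 s | rate /min: 0 / 0.5; amplitude °: – / 0.5 ± 0.3 |
| spikes | raised-cosine translation pulses, random unit direction, 2 s | rate /min: 0.02 / 0.2; amplitude mm: 2 ± 1 |
| jitter | AR(1) noise on all six parameters (coefficient 0.9) | sd: 0.02 mm, 0.01° / 0.05 mm, 0.03° |

Rotations are composed through unit quaternions, so every generated
transform is rigid by construction. Event amplitudes are lognormal
(matching the stated mean and sd, guaranteeing positivity); pulse
shapes are raised cosines (smooth and compactly supported); onsets are
Poisson. These distributional forms, and the nod (3 s) and spike (2 s)
durations, are simplicity-driven modelling choices, not measured
values. The GA/awake profile defaults are calibration choices placing
cohort summaries in a clinically plausible range (awake patients
roughly three times the displacement of anaesthetised ones, drift out
of the bore dominating, nodding only while awake); they are labelled
as such and are not measurements.

Cohorts are drawn with deterministic per-patient seeds from a master
seed; each patient's rates, amplitudes and jitter scales are multiplied
by lognormal factors with `sdlog = 0.4`, a spread that keeps groups
overlapping but separable at the default effect sizes — again a
population-model choice, since per-patient distributions are not
published anywhere.

The default schedule holds five MR windows with standard structural
protocol durations (MPRAGE 266 s, STIR 174 s, FLAIR 272 s and 164 s,
Blade 122 s — 998 s of MR time), interleaved with PET and dead-time
gaps to a 41.7 min wall time, MPRAGE first and flagged as reference.

**What the generator does not emulate:** real tracker noise spectra and
outliers, slow re-seating of the head after large movements,
anaesthesia-depth dynamics, scanner vibration, or any coupling between
motion and image quality. Passing tests therefore certify the
*pipeline* — algebra, masking, metrics, statistics — under controlled
motion with known truth; they do not certify population-level claims
about real cohorts.

## Numerical choices

* Rotations are validated to orthonormality and unit determinant within
  $10^{-9}$; composed rotations drifting beyond that are projected onto
  the nearest rotation (SVD, determinant forced to +1).
* Pose logs store scalar-first unit quaternions so rigidity is
  enforceable at parse time: norms off by up to $10^{-3}$ are
  renormalized, beyond that the row is rejected. A 16-column row-major
  matrix dialect is also read, with projection and a warning above
  $10^{-6}$ deviation.
* All file round trips are lossless at $10^{-9}$ (12 significant digits
  in text output); JSON reports have fixed key order, so runs are
  byte-reproducible at a fixed seed.
* Degenerate inputs: empty masks, missing reference windows, two-group
  requirements, and all-tied samples (p = 1, flagged) raise errors or
  flags rather than silent results.

## Validation problem sizes

The shipped validation suite simulates at 2–5 Hz rather than the
device's 30 Hz: displacement metrics are insensitive to sampling rate
(the 30 Hz closed-form drift check in the suite confirms the
asymptotics), and the smaller traces let the null-calibration study run
200 cohort replicates. The acceptance script analyses the default
18 + 43 cohort at 5 Hz. These sizes are the package's own validation
design; all entry points accept `rate_hz = 30`.

## Known limitations

* The Euler convention of any particular tracking device may differ;
  exact replication of a device's decomposition is not possible in
  general, only of its rigid transforms.
* The motion-free statistic treats capped gaps as representative time;
  with pathologically sparse sampling it degrades toward a sample
  count.
* The KS normality check with estimated parameters is conservative; it
  is used as a reporting justification, not as a gatekeeper.
* Region-level absolute results depend on the centroid table supplied;
  the shipped table is a synthetic placeholder for testing, not
  anatomy.
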