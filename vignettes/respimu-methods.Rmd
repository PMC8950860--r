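---
title: "Methods: estimating respiratory parameters from a trunk IMU network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating respiratory parameters from a trunk IMU network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind **respimu**, the
assumptions of its synthetic-data generator, the tunable parameters and
their defaults, the numerical choices, and the known limitations — in
particular what the physics of the acceleration-norm signal family implies
for model validation on synthetic cohorts.

## 1. The measurement model

### Optoelectronic plethysmography (OEP)

The anterior chest wall of a supine subject is sampled by 45 reflective
markers on a 7 × 7 grid: rows A (clavicles) through G (anterior iliac
spines), columns J–P with M on the midline; the corner columns are absent
in rows A and G. The wall is triangulated into 64 non-overlapping
triangles arranged mirror-symmetrically about the midline: each of the
four interior row gaps contributes 6 quadrilaterals (12 triangles) and the
two boundary strips triangulate the central four column gaps (8 triangles
each). Within a quadrilateral the diagonal runs toward column M, mirrored
across the midline, which makes the triangulation exactly symmetric.

Each triangle contributes a vertical prism volume: the area of its
horizontal projection times the mean height of its vertices above the bed
plane. Because the downstream analysis uses only demeaned frame-by-frame
volume *variation*, the choice of reference plane is immaterial — two
reference heights yield volume series differing by a constant, which the
test suite asserts. Triangles between rows A and E (44 of them) form the
rib-cage compartment (RC), those between E and G (20) the abdominal
compartment (AB), so `V_CW = V_RC + V_AB` holds exactly by partition.

### Preprocessing and time alignment

Marker gaps are filled by cubic-spline interpolation (gaps longer than
`max_gap = 0.5 s` or at the series edges are refused). All marker and IMU
channels are low-pass filtered at `prefilter_cutoff = 10 Hz` with a
zero-lag (forward–backward) 4th-order Butterworth filter; markers are then
spline-upsampled from 50 Hz to the IMU rate of 100 Hz. The two streams run
on independent clocks; the offset is estimated as the lag maximising the
normalised cross-correlation between the second time derivative (central
differences) of the vertical coordinate of the marker on IMU 1 and that
IMU's z-acceleration, inside a window containing the quasi-impulsive tap
artefacts recorded at trial start. Differentiation follows filtering
because it amplifies exactly the noise the filter removes; this
stabilises the correlation peak. After shifting and cropping to the
common overlap, the first `sync_window = 6 s` are discarded so the taps
cannot contaminate volumes, PCA or model training (volumes are computed
after this crop).

### Sensor selection

For each trial the IMU outputs are pooled into eight homologous T × 9
matrices: the three acceleration components, the acceleration norm
(`A_ToT`), and the gyroscope equivalents. Each matrix is z-scored and
decomposed by an eigendecomposition of its correlation matrix. Loadings
are *correlation-scaled* (eigenvector × √eigenvalue), so that a loading is
the Pearson correlation between an observed channel and the unit-variance
PC score, and a squared loading is a shared-variance fraction. This is the
only scaling under which the selection threshold's arithmetic works:
0.32² = 0.1024, i.e. slightly more than 10 % shared variance. Plain
eigenvector entries would not satisfy it.

Per trial and per target volume (CW, RC, AB), the PC whose score best
correlates with the volume (in absolute value) is retained, and its sign
is flipped if needed so the reported ρ is non-negative — PC signs are
arbitrary and only positive correlations are meaningful to report. Scores
and volumes are compared after 2.5 Hz zero-lag filtering and demeaning
(the model-stage conditioning), while the PCA itself runs on the
10 Hz-filtered signals; the retention step's filtering is a documented
choice, as the stage order admits either reading. Absolute loadings of
the retained PCs are averaged across all subjects and trials, and
(family, IMU) pairs with mean |loading| ≥ `loading_threshold = 0.32` are
selected.

### Volume models and validation

Two fixed mass-scaled linear models map IMU signals (2.5 Hz-filtered,
demeaned) to compartmental volumes: Model 1 uses the acceleration norms of
IMUs 7 and 9 (CW, RC) plus IMU 5 (AB); Model 2 uses the y-accelerations of
IMUs 7 and 9 for all compartments. Body mass enters as a multiplicative
factor, absorbing the monotone relation between mass and volume capacity.

Training minimises the Euclidean norm of the vector of per-trial RMSDs
between measured and estimated volumes. Squaring the objective shows it is
a weighted least-squares criterion with weights 1/T per trial, so the
global optimum is available in closed form for any mix of trial lengths;
the package initialises a derivative-free Nelder–Mead simplex search at
that solution and keeps whichever point scores better (the simplex then
serves as a verification step; its collapse onto the optimum is treated as
convergence). Convergence uses a relative tolerance of 1e-9 with a cap of
1e5 evaluations. Each compartment is trained independently, as the model
equations share no coefficients across compartments. When regressors are
exactly collinear (possible on noise-free synthetic data) the closed-form
step falls back to the minimal-norm pseudoinverse solution.

Validation is leave-one-out cross-validation at the *subject* level: both
repetitions of the held-out subject are excluded from training (34 RMSD
entries per default-cohort fold), predicted, and scored.

### Breath metrics

Breath cycles are segmented from the relative minima (inhalation onsets)
and maxima (exhalation onsets) of the filtered, demeaned volume channel.
Two robustness guards, both exposed in the configuration and disabled by
setting them to 0, screen candidate extrema: a minimum topographic
prominence of `peak_prominence_sd = 0.2` × channel SD, and a minimum
separation of `peak_min_distance = 1 s` between same-type events.
Alternation is enforced by keeping the more extreme of adjacent same-type
events; a leading maximum is dropped so event lists start at an
inhalation onset, and only complete min–max–min cycles contribute.
RR defaults to 60 / mean(min-to-min period) rather than a raw event count,
avoiding partial-cycle bias; a count-based variant is available
(`rr_from = "count"`), and the two differ by less than one cycle per
window. Relative errors are `100 · (estimated − measured) / measured` on
trial-averaged parameters; cohort summaries report n, mean, SD, |mean| and
mean |·| per group.

## 2. The synthetic-cohort generator

The generator is a first-class, tested component that stands in for the
study conditions: 18 subjects (7 F, 11 M), two ~2-minute supine trials
each. It emulates:

* **Anthropometrics.** Body mass ~ Normal(57.3, 9.0) kg for females and
  Normal(74.0, 11.4) kg for males, truncated below 35 kg; heights from the
  matching normals. The torso template scales isotropically with
  (mass/70)^(1/3), so that mass-cubed geometry makes the mass-scaled
  linear model well-specified across subjects.
* **Breathing.** Subject-level rates ~ Normal(14, 2) breaths/min truncated
  to [10, 18] — the stated cohort span read as roughly mean ± 2 SD, with
  resting adults clustering at 12–16. Chest-wall tidal excursion is
  8.3 mL/kg (quiet-breathing tidal volumes are ~7–8 mL/kg), the abdomen
  contributing 60 % in the supine posture; the rib cage lags the abdomen
  by 0.2 rad. The waveform is a fundamental plus a 4 % second harmonic
  (inhalation slightly shorter than exhalation), with cycle-to-cycle
  period and amplitude jitter of CV 3 % and 5 %.
* **Kinematics.** Node vertical displacement is
  `baseline + w_RC(t)·φ_RC + w_AB(t)·φ_AB` with raised-cosine mode shapes
  supported on each compartment's rows and zero at the compartment
  borders; the abdominal shape also tapers laterally to zero at the
  midaxillary columns. Because only the vertical coordinate moves,
  compartment volume is *exactly* linear in the mode amplitudes, and the
  waveforms are calibrated through the mesh so OEP on noise-free markers
  reproduces the target tidal excursions to machine precision — this is
  the generator/analysis consistency contract the tests assert.
* **Inertial readings.** Each IMU is oriented by the local surface
  (z along the normal, x cranial); its accelerometer reads the specific
  force `Rᵀ(g e_z + z̈ e_z)` plus white noise, its gyroscope the surface
  tilt rate plus noise. A static, level IMU therefore reads +9.81 m/s² on
  z. Noise defaults are instrument-class: accelerometer 0.0085 m/s² per
  sample at 100 Hz (≈ 1.2 mm/s²/√Hz), gyroscope 0.01 rad/s, marker
  coordinates 0.3 mm with a 5·10⁻⁴ per-frame dropout probability (no
  dropouts in the first/last 0.5 s, since edge gaps are unfillable).
* **Synchronisation artefacts.** Three raised-cosine tap pulses (6 mm,
  0.12 s) on the IMU-1 node within the first ~4 s, injected consistently
  in both streams; a clock offset uniform in ±1 s separates the streams
  and is recorded in the ground truth so lag-recovery accuracy is
  checkable.

What the generator does **not** emulate: posture changes and body-motion
artifacts, pathological breathing patterns, sensor bias/scale errors and
mounting misalignment, soft-tissue artefacts, and posterior-wall motion.
Passing tests therefore demonstrate correctness of the pipeline under the
stated breathing-mechanics model, not robustness to every property of
real recordings.

## 3. What the acceleration norm can and cannot carry

The lateral (y) accelerations are gravity-tilt projections: for a surface
slope s(t), `A_Y ≈ −g·s(t)`, which is linear in the displacement for
narrow-band breathing. This is the mechanism that makes the A_Y-based
model essentially exact on this generator, and the package's tests verify
|ρ| > 0.99 between the filtered lateral abdominal channel and the
abdominal waveform on noise-free trials.

The acceleration *norm* is different. Rotations preserve the Euclidean
norm, so for a reading `Rᵀ(g e_z + a)` the norm is `‖g e_z + a‖ ≈ g + a_z`
— the gravity-tilt term cancels identically, and the only
volume-correlated content of `A_ToT` is the vertical inertial
acceleration, `z̈ ≈ −ω² · displacement` for narrow-band motion at angular
frequency ω. Two consequences follow for the A_ToT-based Model 1 on any
generator faithful to this physics:

1. **Correlation is preserved, gain is not.** `z̈` correlates almost
   perfectly with the volume within a trial (correlation is
   scale-invariant), so PCA-stage correlations for the A_ToT family are
   high. But the signal's *gain* scales with ω²: a single cross-subject
   coefficient cannot fit subjects breathing at different rates, which
   inflates the spread (and, through Jensen-type averaging, the bias) of
   held-out tidal-volume errors roughly in proportion to the cohort's
   variance in squared breathing rate.
2. **The inertial signal is small.** At quiet-breathing amplitudes
   (~1 cm surface excursion) `z̈` is of order 0.01–0.02 m/s², so with
   instrument-class noise the estimated volume series carries an in-band
   noise fraction of 10–30 %. Extrema-based segmentation on such series
   finds spurious cycles on the flattened waveform shoulders, inflating
   extrema-counted respiratory rates for the slowest, lightest subjects.

Both effects are intrinsic to the acceleration norm under this
measurement model — not artefacts of tolerances or tuning — and they are
why, on the synthetic cohort, the A_Y-based Model 2 dominates the
A_ToT-based Model 1 across every reported metric, by margins the
acceptance script quantifies on each run. On real instruments the norm can
additionally pick up effects this generator deliberately omits (per-axis
bias and scale-factor error couple tilt back into the norm; sensor cases
rock on soft tissue), which plausibly explains why A_ToT-based estimation
can perform better on real recordings than rotation-invariance alone
predicts. The generator keeps the faithful physics rather than
introducing instrument imperfections whose magnitudes would be
unconstrained guesswork.

## 4. Numerical choices

* **Filtering.** Butterworth designs come from `signal::butter`; the
  forward–backward pass is implemented with odd-reflection padding of
  three filter lengths *and* steady-state initial conditions (the filter
  has unit DC gain, so the steady state for a constant input is that
  constant). Without the steady-state initialisation, channels with large
  offsets — e.g. y-accelerations near −g·sinθ ≈ −3.6 m/s² — acquire edge
  transients at low cut-offs that corrupt correlations.
* **Resampling and gap filling** use interpolating cubic splines
  (`stats::splinefun`), which reproduce polynomials up to degree 3 exactly
  and reproduce original samples at coincident timestamps.
* **Lag search** scans integer lags over ±(max offset + 0.3 s) and demands
  a peak normalised cross-correlation ≥ 0.5; below that the trial is
  rejected as lacking a synchronisation artefact.
* **PCA** uses `eigen()` on the correlation matrix; scores are
  unit-variance, and eigenvalues below 1e-12 yield zero scores rather
  than dividing by ~0.
* **Degenerate inputs.** Zero projected-area triangles contribute zero
  volume with a warning; constant IMU channels are refused at the
  z-scoring step with the channel named; monotone volume channels (no
  cycles) and channels with fewer than two complete cycles raise errors.
* **Serialisation.** Trial CSVs are written with 17-significant-digit
  decimal text and re-parsed with R's correctly rounded `strtod`, so a
  written trial reloads bit-for-bit.

## 5. Problem sizes

The unit-test suite exercises the full pipeline on small cohorts (three
subjects, 45–60 s trials) so that it completes in about two minutes; the
acceptance-level checks and `scripts/acceptance.R` run the complete
default configuration — 18 subjects × 2 repetitions × 120 s, the
34-equation training folds, and both models under LOOCV — which takes a
few minutes on one CPU. All randomness flows from a single configured
seed; equal seeds reproduce cohorts, selections and fits exactly.

## 6. Known limitations

* The mesh topology is reconstructed from the grid's printed constants
  (45 markers, 64 triangles, midline symmetry); the diagonal orientation
  within quadrilaterals is a convention, and demeaned volume variation is
  insensitive to it at first order.
* The IMU-to-grid-node assignment is a documented convention
  (`imu_node_map()`): IMU 1 on the upper sternum, IMU 5 at the lower
  costal margin's midline, IMUs 7/9 lateral on the abdomen.
* The ~13 mm marker offset introduced by mounting markers on IMU cases is
  ignored, as it shifts volumes by a constant.
* Constant clock offset only; drift between the streams is out of scope.
* Inferential statistics (ANOVA families, normality tests) are out of
  scope; summaries are descriptive.
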