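---
title: "kinfant: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinfant: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfant)
```

# Overview

`kinfant` turns per-frame 2D pose keypoints of supine infants into a
38-dimensional kinematic feature vector, trains an imbalance-aware binary
classifier of fidgety-movement status (FM−, the cerebral-palsy risk
marker, is the positive class), and evaluates it threshold-free under
lock-box discipline. This vignette records the model assumptions, the
parameters that matter, the numerical edge-case rules, and the design
choices that were genuinely open — so a maintainer can tell deliberate
decisions from accidents.

# Preprocessing model

The pipeline assumes a top-down view of a supine infant, one infant per
video, and pose-estimator output on the COCO-17 skeleton in image
coordinates (origin top-left, y down, pixels, 0-based frames).

Stages, in fixed order:

1. **Best detection.** One detection per frame, by the detector's instance
   score; when a candidate has no score, the mean keypoint confidence is a
   deterministic fallback. Frames with no candidate become all-missing and
   are handled by interpolation.
2. **Confidence masking** (`confidence_threshold`, default **0.8**).
   Masking operates per (frame, keypoint) *cell* by default rather than
   per frame: one occluded wrist should not erase the ankles. A
   whole-frame mode (`mask_mode = "frame"`) is available because the
   upstream convention is ambiguous between the two readings. Retention
   (retained cells / all cells) is recorded before interpolation; cohorts
   are expected to retain > 90%.
3. **Linear interpolation.** Interior gaps are filled linearly per
   coordinate; leading/trailing gaps are extended from the nearest
   observed value — extension avoids inventing motion at the video edges.
   A keypoint observed in fewer than two frames is unrecoverable and is an
   error, not a silent fill.
4. **Rolling median** (`median_window_s`, default **1 s**) then
   **rolling mean** (`mean_window_s`, default **1 s**). Windows are
   centered, measured in seconds, converted with the video's own frame
   rate, forced to an odd frame count (unique middle element), and shrink
   at the boundaries instead of padding. Whether the original convention
   was centered or trailing is unstated; centered windows introduce no
   phase lag, which matters for the lagged cross-correlation features.

The 1-s windows imply an effective low-pass cutoff near 1 Hz. Much of the
0.5–4 Hz movement band is therefore attenuated before feature extraction.
This is inherited deliberately: it is the published preprocessing, and its
smoothing-sensitivity is explicitly left out of scope here.

# Pose normalization

Per frame, the mid-hip point is translated to the origin and the pose is
rotated so the mid-hip → mid-shoulder axis points "up". "Head-up" is
anchored on the torso axis, not on facial keypoints, which are the least
reliable in infants. The scale is the per-video **median** torso length,
applied uniformly to all frames: per-frame rescaling would distort
within-video amplitude dynamics, which are exactly what the features
measure. After normalization the median torso length is 1 by construction.

The wingspan-to-body-length QC ratio is the per-frame x-range over y-range
of the 12 non-facial body joints, averaged over frames (the temporal
aggregation of the original measure is unstated; per-frame averaging is
the variance-reducing choice). Top-down supine cohorts concentrate near
0.77 ± 0.12; the flag band default is [0.53, 1.01] (mean ± 2 SD).

# The 38 features

Two blocks, with statistics alphabetical within each joint block so the
column order is a stable cross-site contract (`feature_names()`):

* **Position block** — wrists and ankles, 12 features per pair: per axis
  (x, y), median position, IQR position, median |velocity|, IQR velocity,
  IQR acceleration, each averaged over left and right; plus two bilateral
  statistics: entropy of 2D endpoint speed and maximum lagged
  |cross-correlation| of left/right speed.
* **Angular block** — elbows and knees, 7 per pair: mean and SD of the
  interior joint angle, median |angular velocity|, IQR angular velocity,
  IQR angular acceleration, angle entropy, left/right angle
  cross-correlation.

The 5-per-axis + 2-bilateral split of the position block is the unique
natural reading consistent with 12 features per extremity pair; it is a
reconstruction, and the feature dictionary (`feature_dictionary()`)
documents the mapping so it can be remapped if a reference enumeration
surfaces.

Units: positions in torso units, time in seconds (so velocities are torso
units/s), angles in degrees, entropy in bits, cross-correlations
dimensionless in [0, 1].

Conventions that needed a decision:

* **"Median velocity" means median |velocity|.** The signed median is ≈ 0
  by symmetry and carries no "typical speed" meaning.
* **Entropy estimator**: binned Shannon entropy, **50 bins** over the
  robust [q01, q99] range (values outside are clipped into the end bins),
  computed per side and averaged left/right. Pooling left + right into one
  histogram was rejected: a static but slightly asymmetric pose would get
  ~1 bit from pooling, violating the rule that a static pose has all
  entropies exactly 0. A range below `1e-9 · max(1, |q01|)` counts as
  constant (entropy 0) so that float-level ripple from the rolling filters
  is not mistaken for signal.
* **Cross-correlation**: maximum over integer lags |τ| ≤ `max_lag_s` ·
  fps (default **0.5 s**) of the absolute Pearson correlation on the
  overlap; ties prefer the smaller |lag|. A series whose SD is below
  `1e-9 · max(1, |mean|)` is defined to have correlation 0 (flagged).
* **Joint angles**: interior angle at the joint vertex via the clipped
  arccos of the normalized dot product, range [0°, 180°]; zero-length
  segments give an undefined frame that is interpolated from neighbors
  and counted.
* **Derivatives**: central differences scaled by fps, one-sided at the
  endpoints; acceleration is the velocity operator applied twice.
* **Windowed variant**: 2-s windows, 50% overlap, covering the whole
  video including rest; the last partial window is dropped. Whole-video
  features are the model inputs; the windowed table is an export product.

# Splits, manifests, lock-box

Splitting is subject-wise, never record-wise — record-wise splitting leaks
subject identity across splits and inflates performance estimates.
Stratification cells are label × sex; within each cell, members are
shuffled by the seeded generator and allocated to Train/Val/Test by
largest-remainder rounding (default fractions 0.70/0.10/0.20). Cells
smaller than the number of splits trigger a logged fallback to label-only
stratification, and a size-preserving repair guarantees at least one
member of each class per split whenever the cohort allows it. Age and
ethnicity balance, where provided, is reported post hoc rather than
enforced: exact multi-way stratification is infeasible with tens of
positives.

The manifest (id lists, fractions, sizes, prevalences, seed) is serialized
as canonical JSON — sorted keys, sorted ids, no timestamp — and hashed
with SHA-256. Freezing is therefore byte-reproducible, verification
(`verify_manifest()`) is exact, and the freeze time lives in the run log
instead of the manifest. Evaluating the Test split requires
`unlock = TRUE`; every unlock is logged. The lock-box is a procedural
discipline in the original design; here a tool can make it structural.

# Classifier

The training contract mirrors what a constrained AutoML run provides:
**balanced accuracy** as the objective (at ~10:1 imbalance plain accuracy
is uninformative), internal stratified cross-validation (default **k = 5**,
clamped to the minority count), inverse-prevalence class weights (or
seeded minority oversampling), and a **single final model** — no
ensembling, which tends to overfit when selection repeatedly adapts to
validation results.

The builtin candidate family is small and fixed: elastic-net logistic
regression (α ∈ {0, 0.5, 1} × 5 log-spaced penalties, via `glmnet`) and
gradient-boosted decision stumps (learning rate ∈ {0.1, 0.3}, rounds ∈
{50, 150}). The stump booster is implemented in the package because no
boosted-tree package exists in the supported environment; it minimizes
weighted binomial deviance with a vectorized exhaustive split search over
per-feature octile cuts and is fully deterministic. Standardization and
median-imputation statistics are computed **within each training fold
only** and stored from the full training set for prediction time — never
from evaluation rows (the anti-leakage tests exercise exactly this).
Scores are native class probabilities; no recalibration is applied, since
threshold/calibration stability across splits is known to be fragile and
is reported rather than patched.

An `automl` backend hook (`train_config(backend = "automl", automl_fn =)`)
lets users delegate to an external engine under the same seed contract.

# Evaluation machinery

* **ROC-AUC** is computed from ranks, so tied scores receive half credit
  and the area equals the Mann–Whitney concordance probability exactly.
  The decision rule everywhere is `score ≥ t ⇒ positive`.
* **PR-AUC** uses the step-wise average-precision rule — no linear
  interpolation, which is known to be optimistic in PR space. With
  constant scores it equals the prevalence, the chance baseline.
* **Youden's operating point** maximizes TPR − FPR; ties break toward the
  *larger* threshold, i.e. fewer infants flagged — the lower
  screening-burden choice. Threshold selection on the evaluation split
  itself carries optimistic bias; the package exposes the computation and
  leaves the discipline to the analysis plan.
* **Permutation importance**: ΔROC-AUC per feature over `n_repeats = 10`
  seeded permutations on a held-out set, grouped by joint; group
  percentages are computed from unrounded totals.
* **Scaling analysis**: a fixed stratified test set is held out; for each
  training size the procedure is retrained on seeded stratified
  subsamples (default 6 per size) and the mean test AUC is fit by OLS in
  log(1 − AUC) vs log(n). On inputs constructed exactly as
  1 − c·n^(−β) the slope estimate is −β to numerical precision.

# The synthetic generator

The generator emulates the *statistical structure the pipeline assumes*,
not infant biomechanics: supine top-down geometry at 1280×720; limb
endpoints driven by unit-RMS sums of K random sinusoids in **0.5–4 Hz**;
movement bursts (Gaussian bumps, ~0.5/s per limb pair) and rest bouts
gating the motion; per-keypoint confidence ~0.95 with dropout events below
0.8 (probability 0.05 per cell); single-frame spikes (probability 0.01,
±120 px); occasional spurious second detections (probability 0.02 per
frame); mixed frame rates 15/30/120 weighted 3:1043:7; durations 60–120 s;
FM− prevalence 0.11. These defaults reproduce the acquisition regime the
pipeline targets (mostly-30-FPS handheld recordings retaining > 90% of
cells at the 0.8 threshold).

The class difference is encoded only along the three axes the feature set
is designed to measure — movement amplitude (and its between-subject
spread), component count (complexity/entropy), and bilateral coupling,
plus rest fraction — never in any fidgety-specific waveform. `effect_size`
interpolates linearly between identical classes (0, the null world) and
the full difference (1): FM+ draws amplitude ~N(45, 14) px, K ∈ 4–6,
coupling 0.2, rest 0.15; FM− at effect 1 draws amplitude ~N(18, 5) px,
K ∈ 1–2, coupling 0.85, rest 0.4.

**Coupling is modelled at two levels.** The first design coupled only the
velocity carriers (mirrored shared component vs independent components).
That is invisible to the pipeline's cross-correlation-of-*speeds* feature
below coupling ≈ 0.9, because speed is a magnitude: correlation of
magnitudes scales roughly with the square of the carrier correlation. The
generator therefore also makes each movement burst *bilateral with
probability = coupling*, which the speed cross-correlation reads out
approximately linearly; at coupling 1 the two sides are exactly mirrored
and the feature reaches ≈ 1.

What the generator does **not** emulate — and hence what a green test does
not establish: realistic limb kinematics or anthropometrics, camera
perspective distortion, pose-estimator failure modes beyond iid jitter /
dropouts / single-frame spikes, within-video developmental or state
changes, or any clinically meaningful FM waveform. Synthetic separability
at effect 1 is nearly perfect by design; clinical cohorts are much harder,
and no synthetic AUC should be read as a performance claim.

# Numerical and testing notes

* **Similarity invariance.** The feature vector is exactly invariant to
  translation, uniform scaling, and rotation of the raw pixels *through
  the normalization stage*, at any angle. Through the full pipeline the
  rotation group is restricted to quarter turns: a coordinate-wise running
  median commutes with axis-aligned transforms but not with arbitrary
  rotations (the median element may be selected differently per rotated
  coordinate). This is a property of the prescribed filter, not of the
  implementation; the invariance tests are split accordingly.
* **FPS robustness.** Resampling the same motion between 30 and 120 FPS
  preserves features to within 5% when the motion band lies below the 1-s
  filters' ~1 Hz cutoff. Near-cutoff components are attenuated
  rate-dependently by the filters themselves, so the robustness test uses
  a 0.05–0.35 Hz band to isolate time-unit correctness from filter
  response.
* **Run-time scaling of the test suite.** The acceptance cohorts (400–900
  subjects) use 60-s videos — the short end of the emulated range — and
  the parameter-recovery sweeps use 90-s videos (the lagged-correlation
  estimator needs enough bursts per video to be stable). The statistics
  under test do not depend on duration beyond estimator noise.
* **Determinism.** Every stochastic step takes a seed; cohort generation
  fans a master seed into per-subject child seeds; training and splitting
  are bit-reproducible given their seeds, and repeated pipeline runs
  produce byte-identical artifacts.

# Known limitations

* The exact published feature enumeration, lag window, and entropy
  estimator are not recoverable from text alone; this package's choices
  are documented above and kept remappable.
* The builtin classifier is a deliberately small, reproducible stand-in
  for a full AutoML search; it preserves the contract, not the search
  breadth.
* KS p-values use the asymptotic series with the Stephens small-sample
  correction and differ from R's exact small-sample computation by up to a
  few hundredths.
* No calibration analysis, decision-curve analysis, or clinician-agreement
  statistics; no pose estimation — the pipeline starts at keypoints.
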