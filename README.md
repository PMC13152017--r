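# kinfant

Kinematic feature pipeline for infant movement screening.

## The problem

Cerebral palsy (CP) is the most common childhood motor disability. The
general movements assessment (GMA) — expert visual scoring of spontaneous
infant movement from video at 3–4 months — is highly predictive of CP, but
depends on scarce trained clinicians. Automated prescreening pipelines
predict the GMA outcome (fidgety movements present, FM+, vs absent, FM−,
the risk marker) from 2D pose-estimated video. Because raw videos and even
keypoint time series are protected health information, what *can* travel
between sites are de-identified kinematic feature tables and open,
untuned pipelines. `kinfant` implements such a pipeline end to end for R,
together with a synthetic keypoint-cohort generator so every stage is
testable without any clinical data.

## What it computes

Starting from per-frame COCO-17 keypoint detections (x, y, confidence,
possibly several candidate detections per frame):

1. **Preprocessing** — keep the highest-confidence detection per frame,
   mask keypoints with confidence < 0.8, linearly interpolate gaps, remove
   outliers with a 1-s rolling median, smooth with a 1-s rolling mean.
   Windows are specified in seconds and converted with each video's own
   frame rate.
2. **Pose normalization** — per frame, translate the mid-hip to the origin
   and rotate the mid-hip → mid-shoulder axis "up"; scale by the per-video
   median torso length, so coordinates are in torso units. The
   wingspan-to-body-length ratio (x-range / y-range of the 12 non-facial
   body joints) serves as a viewing-angle QC proxy.
3. **Features** — the preregistered 38-dimensional vector: for wrists and
   ankles, median/IQR of position, median |velocity|, IQR velocity and IQR
   acceleration per axis (left/right averaged), entropy of endpoint speed,
   and the maximum lagged |cross-correlation| of left/right speed
   (bilateral coordination); for elbows and knees, mean/SD of the interior
   joint angle, median |angular velocity|, IQR angular velocity and
   acceleration, angle entropy, and left/right angle cross-correlation.
   Joint-group counts: wrist 12, ankle 12, elbow 7, knee 7.
4. **Cohort handling** — exclusion-stage accounting, subject-wise
   stratified Train/Val/Test(lock-box) splits (default 70/10/20), and a
   canonical-JSON manifest frozen with a SHA-256 hash.
5. **Classification** — a binary FM− risk model trained under the AutoML
   contract: balanced-accuracy objective (the sensible metric at ~10:1
   imbalance), internal stratified CV, inverse-prevalence class weights,
   one final model. The builtin backend searches elastic-net logistic
   regression and gradient-boosted stumps; an `automl` hook accepts an
   external engine.
6. **Evaluation** — from-scratch ROC/PR curves and AUCs (Mann–Whitney tie
   handling; step-rule average precision), the Youden operating point
   `argmax_t {TPR(t) − FPR(t)}`, confusion matrices at any threshold,
   permutation feature importance grouped by joint (ΔROC-AUC), and the
   learning-curve power law fit of `log(1 − AUC)` on `log(n)`. Evaluating
   the lock-box split requires an explicit unlock, which is logged.

## Worked example

```r
library(kinfant)

co  <- generate_cohort(synth_config(n_subjects = 150, seed = 2026,
                                    duration_range_s = c(60, 60)))
ft  <- cohort_feature_table(co)              # 150 x (id, label, 38 features)
man <- stratified_split(ft$subject_id, ft$label,
                        strata = co$cohort[, "sex", drop = FALSE],
                        seed = 2026)
tr  <- ft[ft$subject_id %in% man$splits$train, ]
model <- train(tr, tr$label, train_config(seed = 2026))

val <- ft[ft$subject_id %in% man$splits$val, ]
sc  <- predict_scores(model, val)
r   <- roc_auc(sc)
youden_threshold(r$curve)
```

Output as printed by this exact script:

```
kin_manifest: train 105 / val 14 / test 31, prevalence 8.6%/7.1%/9.7%
  hash 037ebafbc73bf35f1d4f52c7664818136451d101d8f93644bb7157c4a10caad2
kin_model [builtin]: elastic-net logistic (alpha 0.5, lambda 0.1778), internal-CV balanced accuracy 1.000
Val ROC-AUC: 1.000   PR-AUC: 1.000
operating point: t = 0.8704, TPR 100.0%, FPR 0.0%, J = 1.000
  TP 1  FN 0  FP 0  TN 13
```

The synthetic classes at the default effect size are deliberately well
separated (the generator encodes the class difference in movement
amplitude, complexity and bilateral coupling), so a perfect validation AUC
on 150 synthetic subjects is the expected behavior, not a claim about
clinical data: real cohorts sit far closer to the decision boundary. The
manifest hash freezes the split; `verify_manifest()` refuses evaluation if
the file changed, and `evaluate_on_split(..., split = "test")` refuses to
run at all without `unlock = TRUE`.

A command-line entry point covering cohort generation and the full
pipeline lives in `inst/cli/kinfant` (subcommands `synth` and `run`
`[--unlock]`).

## Documentation

The methods vignette (`vignettes/kinfant-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical edge-case rules, and known limitations.
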