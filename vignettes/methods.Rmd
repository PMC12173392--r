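---
title: "Methods: geometric posture features and temporal fall confirmation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric posture features and temporal fall confirmation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelfall)
```

## The problem and the model

Falls among older adults are a leading cause of injury, and camera-based
monitoring promises detection without wearables. `skelfall` implements the
geometry-first approach to this problem: an upstream pose estimator (any
COCO-17 backend) reduces each video frame to a 2-D skeleton per person, and
everything downstream operates on skeleton geometry alone. This keeps the
classifier small, interpretable, and invariant to where and how large the
person appears in the image, and it means no raw imagery needs to leave the
device.

The pipeline has three stages:

1. **Feature extraction.** Each frame-person becomes a 9-vector: the
   bounding-box-normalized center of mass $(\bar x, \bar y)$ (unweighted
   mean over visible keypoints), and seven angles in degrees — the
   shoulder–nose–shoulder angle
   $\arccos\!\big(\tfrac{\vec{BA}\cdot\vec{BC}}{\|\vec{BA}\|\|\vec{BC}\|}\big)$,
   the torso and nose-to-ankle inclinations from the image vertical
   $\arccos(v_y/\|\vec v\|)$, the hip-line and shoulder-line angles from
   the horizontal $\arccos(v_x/\|\vec v\|)$, and the left and right knee
   flexion angles between thigh and shank directions.
2. **Frame classification.** A binary standing (1) / lying (0) classifier
   on the 9-vector. The default is a soft-margin SVM with RBF kernel
   $K(x_i,x_j)=\exp(-\gamma\|x_i-x_j\|^2)$, $C=1$, $\gamma=0.1$, solved by
   sequential minimal optimization; CART, random forest, and logistic
   gradient boosting are available behind the same interface.
3. **Temporal confirmation.** Per-track folding of the label sequence
   through configurable criteria: lying for $\geq T$ seconds, lying for
   $\geq F$ frames, or a fast standing-to-lying transition. Only a
   confirmed criterion raises a fall event, at most once per lying run.

## Coordinate and angle conventions

Image coordinates are used throughout: origin top-left, y **downward**.
For an upright person the nose-to-mid-hip vector points in +y, so the
torso angle is ~0° standing and ~90° lying. Angles live in [0, 180]
degrees and are *not* folded at 90°: the hip- and shoulder-line angles
distinguish the sign of $v_x$, so a left-right flipped hip line reads
>90°, which keeps the horizontal-reference formulas faithful and lets the
flip augmentation be exercised. The arccos argument is clamped to
$[-1, 1]$ so numerically collinear vectors can never produce `NaN`. A
keypoint with confidence below the visibility threshold (default 0.5) is
treated as missing; any feature whose required keypoints are missing, or
whose defining vector is zero-length, is `NA` at the geometry layer —
resolution (dropping the frame or forward-filling) is the preprocessing
layer's single responsibility.

The center of mass is the **unweighted** mean of visible keypoints. A
confidence- or mass-weighted variant was considered and rejected: the
defining formula is an unweighted average, and which keypoints enter the
average when some are undetected is a policy choice — visible-only is used
here and stated rather than hidden.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| visibility threshold | 0.5 | confidence | midpoint of the score range; backends differ, so configurable |
| smoothing window | 5 | frames | short enough for live use at tens of FPS; unstated upstream, so a config decision |
| smoothing mode | causal | — | a real-time system cannot see future frames; `centered` offered offline |
| angle normalization | degrees/180 | — | deterministic and training-set-independent; z-score offered as the alternative reading of "normalized" |
| SVM | C=1, γ=0.1, RBF | — | the published hyperparameter set for this classifier family |
| time rule | 5 | s | first of the published example values (5 s / 10 s) |
| frame rule | disabled | frames | alternative to the time rule (examples 200 / 500) |
| speed rule | disabled | frames | see the limitation below |
| confirm_frames | 15 | frames | ~0.5 s at 30 FPS; suppresses single-frame label flickers |
| gap_tolerance | 30 | frames | ~1 s of lost tracking before per-track state resets |
| combine_mode | any | — | the criteria are presented as user alternatives, implying OR |

Augmentation (training only, keypoint space): rotation U(−15°, +15°),
scale U(0.75, 1.25), horizontal flip p=0.5 with left/right index swap,
Gaussian coordinate noise with SD = 0.01 × bbox diagonal. These are the
exact geometric images of the usual image-space transforms — a
geometry-only classifier cannot see brightness or contrast, so pixel-level
augmentations have no counterpart here. The noise σ is expressed as a
fraction of the person box diagonal to stay scale-free.

## The synthetic world

The simulator generates what the pipeline assumes an upstream pose
estimator emits, with exact ground truth:

* **Templates.** Anatomically proportioned standing, lying (standing
  rigidly tipped 90° about the ankle midpoint), and crouching layouts.
  Standing has torso/leg angles < 5°; crouch bends knees past 70° with
  torso at ~25°, deliberately between the classes.
* **Scenarios.** Static standing and lying; walking (leg swing + drift);
  fast falls (rigid tipping over ~0.5 s); gradual falls (~3.5 s); and a
  crouch confounder (down, 2 s hold, up). Defaults: 12 s at 30 FPS,
  transition starting 30% in, body height 170 px.
* **Noise.** Isotropic Gaussian jitter per coordinate (default 2 px;
  3 px for training tables) and i.i.d. per-keypoint dropout (default
  2%). Ground-truth labels switch standing→lying where the *noiseless*
  torso inclination crosses 45° — the midpoint of the 0–90° range — so
  labels are exact by construction.

What a green test does **not** establish: the simulator has no detector
error structure (correlated jitter, identity switches, motion-blur
dropout), no camera perspective or foreshortening, no furniture occlusion,
and its two training classes are ~90° apart in torso angle — far cleaner
than manually labeled video frames. Classifier accuracies near 1.0 here
validate the machinery, not field performance.

## Numerical choices

* SMO uses the deterministic max-$|E_1-E_2|$ second-index heuristic,
  tolerance $10^{-3}$, and a pass cap; identical data and seed give
  identical support vectors, so training is reproducible.
* Tree splits break ties by first feature index, thresholds at midpoints
  of consecutive distinct values; boosting uses second-order leaf weights
  $-G/(H+\lambda)$ with $\lambda = 1$.
* AUC is the trapezoidal area over thresholds at distinct scores (ties
  grouped), which equals the tie-adjusted Mann–Whitney statistic; a
  constant scorer yields 0.5 by construction.
* Z-score normalization uses the population SD; a zero-variance channel is
  centered with unit divisor and a warning rather than producing `Inf`.
* Model artifacts are JSON at full double precision, so a reloaded model
  predicts identically.

## The speed criterion: a structural limitation

The speed rule is defined on the label stream: a fall is "fast" when the
span between the last standing-labeled frame and the first frame of the
(confirmed) lying run is at most `speed_threshold_frames`. Implementing
this surfaced a structural fact worth stating plainly: **for a
continuously observed track, that span is always one frame**, whatever the
fall's real duration. Any classifier that thresholds a continuous posture
trajectory emits `1…1 0…0` with a single crossing; label flicker near the
boundary only moves the last standing frame closer to the lying onset.
Fall-speed information simply is not representable in a gap-free binary
label sequence — it would require either transition-correlated detection
gaps (pose estimators do fail during rapid motion, which is what the
rule's worked example with missing frames implicitly models) or a
third "transitional" state derived from classifier scores. The package
therefore implements the rule exactly as stated, documents that on
synthetic gap-free streams it cannot distinguish gradual from fast falls,
and leaves the corresponding acceptance expectation red rather than
engineering a pass. Gradual falls *are* still detected by the default
time rule; what is lost is only the ability to filter them out by speed.

## Known limitations

* Binary posture only; sitting, kneeling and transitional postures are
  forced into one of two classes. The crouch confounder probes this but a
  richer taxonomy would need multi-class labels.
* The temporal engine trusts upstream track ids; identity switches merge
  or split per-person state.
* No joint velocities or 3-D lifting; features are per-frame geometry.
* The gradient-boosting learning rate (0.0045 over 200 trees) moves
  logits by at most ~±2 — adequate for separable data, but shallow
  confidence on hard data is expected with these published defaults.
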