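---
title: "Scoring movement quality from webcam pose landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring movement quality from webcam pose landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(rehabdtw)
library(dplyr)
```

## The problem

Home rehabilitation programmes for upper-limb impairment (post-stroke
hemiparesis, frozen shoulder) need an objective measure of how well a patient
performs a prescribed exercise, without clinical equipment. A common webcam
plus a pose estimator yields a stream of 33 two-dimensional body landmarks per
frame; from these, `rehabdtw` quantifies the quality of three standard
upper-limb exercises drawn from the Fugl-Meyer Assessment for Upper Extremity
(FMA-UE): shoulder abduction, shoulder flexion and elbow flexion. Only the
`x`/`y` image coordinates are used — the estimated depth coordinate of webcam
pose estimators is unreliable and is deliberately ignored.

The central idea: movement quality can be scored against *healthy* reference
data alone. No patient recordings are needed to build the reference, which
matters because impaired-movement data are scarce and privacy-restricted.

## The model

### Joint angles

Each joint angle is the interior angle at a vertex landmark between the
vectors to two reference landmarks, by the law of cosines:

$$ J = \arccos\!\left(\frac{D}{M_1 M_2}\right)\cdot\frac{180}{\pi}, $$

with $D$ the dot product of the two vertex-anchored vectors and $M_1, M_2$
their magnitudes. The cosine argument is clamped to $[-1, 1]$ so that
floating-point collinearity cannot produce `NaN`. Angles are unsigned interior
angles in $[0^\circ, 180^\circ]$, invariant under translation, rotation and
uniform scaling — so the image-normalized, y-down coordinate convention needs
no correction. The shoulder angle uses the elbow and hip as references, the
elbow angle the shoulder and wrist, and the wrist angle the index finger and
elbow. Whether the hand landmark called "index finger" in the 33-point schema
is what a goniometrist would pick is moot at webcam resolution; we use the
schema's index-finger point.

Angle trajectories are smoothed with a centered moving average of window 5
samples before both segmentation and assessment. The window is truncated at
the trajectory edges so the output keeps the input's length and time grid —
segment boundaries therefore map one-to-one to frames. A window of 1 disables
smoothing for ablation.

### Repetition segmentation

Continuous movement is cut into repetitions ("motion segments") using the
primary joint angle only; the compensation angles of multi-angle feature sets
are sliced with the same frame markers, never re-segmented. The detector is a
small state machine on the deviation from the rest angle (the median over the
initial 0.5 s quiet window):

* **start** — first sample deviating more than 10° from rest, after the angle
  has re-armed by coming back below that threshold;
* **trigger** — first sample after the movement peak, where the angle begins
  returning toward rest (in the source system this fires the game input);
* **end** — first sample after the trigger within 5° of the start angle; if
  the next repetition starts before the angle returns, the local extremum
  between the two closes one segment and opens the next (the boundary frame
  is shared, so segment *interiors* never overlap).

Movement direction is inferred from the first threshold crossing, so the same
detector handles abduction (shoulder angle rises) and elbow flexion (elbow
angle falls). A peak must swing at least 15° (the prominence parameter) to be
confirmed, which keeps tremor-scale oscillation from splitting repetitions;
segments shorter than 0.3 s are discarded. All five numeric defaults are
calibration knobs in `segmentation_params()` — they are not prescribed by the
method, and the right values depend on the exercise and the estimator's noise.

### Baseline construction

The reference ("baseline") for one exercise is built from a sample of normal
segments. Per joint: each trajectory of length $l_i = e_{max,i}$ is linearly
stretched to the mean length $\bar l = \sum l_i / n$ via
$e' = e\,\bar l/e_{max}$, resampled by linear interpolation on a uniform grid
over $[0, \bar l]$, and averaged pointwise. The grid spacing defaults to the
median inter-frame interval of the inputs (≈1/60 s at 60 FPS); the method
text leaves the grid unspecified, and this choice preserves the native
temporal resolution. The combined baseline $B$ stacks the per-joint mean
trajectories in feature-set order.

The baseline also carries distance statistics: the multi-DTW distance of each
contributing segment to $B$ is computed, and $\mu,\sigma$ are their sample
mean and standard deviation ($n-1$; the population convention is equally
defensible but the sample convention matches standard reporting of an
empirical SD). These are *in-sample* statistics — the same segments build the
means and feed $\mu,\sigma$ — which mirrors the published procedure and is
also the mechanism behind the overfitting it reports for the triple-angle
shoulder-flexion variant; `build_baseline(stats_segments =)` accepts a
held-out set to probe that. A baseline with $\sigma = 0$ (e.g. built from
identical segments) is flagged degenerate and refuses to standardize.

### Distance, Z-score, score

A segment $\alpha$ is compared with $B$ by multi-dimensional dynamic time
warping:

$$ d_\alpha = \text{Multi-DTW}(\alpha, B), \qquad
   Z_\alpha = \frac{d_\alpha - \mu}{\sigma}, \qquad
   S_\alpha = \frac{100}{\max(Z_\alpha, 1)}. $$

A segment within one standard deviation of the normal mean scores a perfect
100; beyond that the score decays hyperbolically (50 at $Z=2$, 25 at $Z=4$),
continuous at $Z=1$, with range $(0, 100]$.

The published method does not pin down the DTW variant, so these choices are
explicit in `dtw_config()` and were made once, on first principles:

* **dependent multivariate mode** — one DTW over vector-valued samples whose
  per-step cost is the Euclidean norm of the per-joint differences, all
  joints equally weighted (an independent mode, averaging per-joint DTWs, is
  available; for one joint both collapse bitwise onto plain DTW);
* **symmetric steps** (diagonal/left/up), no window band by default;
* **path-length normalization** — the accumulated cost is divided by the
  optimal warping-path length, defined as the *minimum* length among
  cost-optimal paths so the quantity is well-defined and reproducible. This
  puts distances on the scale of a per-step angular error (a degree or two
  for clean normal movement), the scale on which the published distance
  tables read, rather than a cumulative sum over ~60-frame segments. The
  exact normalization behind the published magnitudes is not recoverable
  without the original recordings; this is a calibration caveat, not a claim
  of numeric equivalence.
* segments are compared at their native sampling against the baseline grid —
  DTW absorbs tempo, so no pre-resampling is applied. A consequence worth
  knowing: a slow movement that reaches the full range of motion scores like
  a normal one. That is aligned with rehabilitation practice (reaching the
  target angles matters more than speed) but it means timing pathology is
  invisible to this score.

Equal joint weighting makes the wrist angle — whose range of motion is small —
relatively sensitive to noise in multi-angle feature sets; `joint_weights`
exposes this trade-off.

## The synthetic study

Because the original participant recordings are private, the package ships a
simulator that reproduces the *protocol* of the validation study and the
qualitative structure of its data, so the full pipeline can be exercised and
tested end to end:

* 12 participants × 3 exercises × 2 sides × (2 normal + 1 abnormal) rounds ×
  10 repetitions = 216 clips and 2160 segments — 720 per exercise (480
  normal + 240 abnormal), 180 per participant;
* normal repetitions: smooth raised-cosine pulses spanning the full range of
  motion (e.g. shoulder 15°→165°), ~1 s each (±10% jitter), ±5% peak jitter;
* abnormal repetitions: 2–3 s (uniform), 70% of the normal range, with a 6 Hz
  tremor of 3° gated by the movement envelope — emulating movement against a
  5-kg resistance band;
* Gaussian sample noise of 0.5° on every angle; per-participant Gaussian
  offsets (SD 5°) on rest and peak angles for inter-subject variability;
* secondary and wrist angles move synchronously with smaller excursions, so
  multi-angle feature sets have real (if idealized) compensation structure;
* a posture-lean knob (`posture_lean_sd_deg`, off by default) adds a per-clip
  offset to the shoulder rest angle, reproducing the sitting-posture
  variability that blurs the normal/abnormal separation for shoulder flexion.

Only the durations, range-of-motion direction, tremor presence and protocol
counts are constrained by the study description; the numeric shape parameters
are this package's own choices of what a plausible recording looks like, and
all are config-exposed. The simulator does **not** model pose-estimator
failure modes (occlusion, identity swaps, out-of-frame limbs), camera
perspective error, or genuinely pathological movement strategies. Passing
tests on synthetic data therefore demonstrate that the pipeline implements
the method correctly and recovers designed-in structure — not that the score
separates real patients from healthy movers.

```{r simulate, eval = FALSE}
dataset <- generate_protocol_dataset(protocol_plan(), seed = 0)
segments <- segment_dataset(dataset)
experiment <- run_experiment(segments, seed = 0)
tidy(experiment)
autoplot(experiment)
```

On the default synthetic study (seed 0) the single-angle comparisons behave
as the method intends: the two normal subsets are statistically
indistinguishable (t and U p > 0.05) while normal–abnormal differences are
overwhelming (p < 10⁻⁴) for all three exercises, and the subset-B Z-scores
have mean 0 and SD 1 by construction. The test suite asserts exactly these
properties; it states nothing about real recordings.

## Numerical and testing choices

* The DTW dynamic program is implemented in C++ (the per-call cost matrix is
  at most a few hundred by a few hundred cells); the test suite checks it —
  including the path-length tie-break — against an exhaustive enumeration of
  all monotone warping paths on instances up to length 6 and 3 joints.
* The Mann–Whitney U-test uses the exact distribution for small tie-free
  samples (verified against a full permutation enumeration at group sizes
  ≤ 7) and the tie-corrected normal approximation otherwise. The t-test is
  the pooled-variance Student test; Welch is behind a flag. No
  multiple-testing correction is applied — the evaluation reports raw
  p-values, deliberately.
* Subset splitting is stratified per participant and exercise, so both
  normal subsets contain every participant equally; left/right sides are
  pooled before analysis.
* Interpolation is exact at knots; queries outside a trajectory's range are
  errors rather than extrapolations. Degenerate geometry (a reference
  landmark coinciding with the vertex) raises an error naming the frame.
* Test problem sizes: the full 216-clip study runs in a few seconds at
  60 FPS; oracle checks use 200 random small DTW instances; property loops
  use fixed seeds throughout.

## Known limitations

* The score is blind to speed and smoothness by construction (see above);
  movement-smoothness or time-penalty features are deliberately out of scope.
* The in-sample $\mu, \sigma$ slightly flatter the baseline subset
  (its own Z-scores are standardized to mean 0, SD 1), which is the published
  behaviour but optimistic relative to a held-out estimate.
* Strict monotonicity of $d_\alpha$ under residual amplification is not
  guaranteed by DTW — a larger deviation can occasionally find a marginally
  cheaper off-diagonal alignment; empirically the distance grows with
  amplification in aggregate, and the suite tests exactly that.
* Landmark visibility values are carried through the IO layer but ignored by
  the mathematics, matching the method's use of raw x/y only.
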