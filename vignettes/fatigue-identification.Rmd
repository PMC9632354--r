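---
title: "Identifying driver fatigue from facial landmark streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying driver fatigue from facial landmark streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowse)
```

## The problem

Drowsy drivers blink slowly, yawn, and lose control of head posture. Given a
per-frame stream of 2D facial landmark coordinates — six eye points, eight
mouth points, and five face points with timestamps — the task is a binary
decision: is the driver fatigued? `drowse` implements the full chain from
landmarks to decision and a synthetic landmark simulator that makes every
stage testable without video data.

The pipeline is:

1. **Geometry** (`extract_features()`): per-frame eye/mouth opening measures
   and head-pose Euler angles.
2. **Denoising** (`fft_smooth()`): zero-phase FFT moving average per feature
   series.
3. **Reduction** (`fit_factor_model()`, `factor_scores()`): 11 features to
   `k` common factors.
4. **Windowing** (`make_windows()`): sliding 900-frame windows, stepped by
   80 frames, each averaged into one sample.
5. **Classification** (`grnn()`, `ga_optimize()`): a generalized regression
   neural network whose smoothing factor is tuned by a genetic algorithm on
   leave-one-out error.

## Features and their conventions

With eye corners $p_1, p_6$ and lid pairs $(p_2,p_3)$, $(p_4,p_5)$:

* **EAV** $= (\lVert p_5-p_4\rVert, \lVert p_2-p_3\rVert)/\lVert p_6-p_1\rVert$
  — the eye aspect vector; scale-free, collapses toward 0 as the eye closes.
* **EOA** $= \arcsin(d_\perp(p_2,\; p_1p_6)/\lVert p_2-p_1\rVert)$ — the
  opening angle of the upper lid against the corner line, in $[0, \pi/2]$.
  The choice of $p_2$ as the lid point is a convention (configurable); any
  lid point preserves the point-to-corner-line structure.
* **S\_ar** $= a'b'/(a_{max} b_{max})$ — the eye fitted-ellipse area ratio,
  with $a'$ the current canthus distance and $b'$ the mean lid-pair distance
  ($\pi$ cancels). The calibration constants are taken as the observed maxima
  of a stream (`calibrate_eyes()`), so the feature is $\approx 1$ fully open.
* **MAV**, **MOA**, **S\_mp** — the mouth analogues: three lip pairs over the
  corner distance, the mid-lip opening angle, and the axis-aligned area proxy
  $|x_{M8}-x_{M1}|\cdot|y_{M7}-y_{M3}|$. S\_mp is translation invariant only;
  the ratio and angle features are also rotation and scale invariant.
* **Pitch/yaw/roll** — recovered by `solve_pose()` (below), in degrees.
* **F\_blink** — the fraction of frames in a window whose mean lid-pair
  distance is below 20% of the calibrated open distance. The 20% cut is the
  P80 convention of the PERCLOS literature; the per-frame closure rule is a
  package convention since only the window-level formula is standard.
* **F\_yawn** — the fraction of frames inside sustained mouth openings: the
  mid-lip MAV component must exceed 0.6 for at least 3 s. The duration gate
  is what separates ~4 s yawns from ~1 s speech bursts; both the gate and
  the threshold are configurable.

For the 11-column feature table the two EAV components and three MAV
components enter as their means (`scalarize()`), keeping one column per
named feature in the fixed order EAV, MAV, S\_ar, S\_mp, Pitch, Yaw, Roll,
EOA, MOA, F\_blink, F\_yawn. Because F\_blink and F\_yawn are window
quantities but the table is per-frame, they are computed as trailing rolling
fractions over the same 900-frame horizon used for classification windows;
the first frames of a stream use the available prefix.

## Head pose

The head is treated as a rigid body: a generic model-centred 3D face model
(five points, millimetres; `default_face_model()`, synthetic) is fitted to
the five observed 2D points under a pinhole camera by minimizing squared
pixel reprojection error. The solver is damped Gauss-Newton with
left-multiplied axis-angle increments, initialized from a
scaled-orthographic (POS) estimate. On noise-free forward projections it
recovers the generating pose to machine precision; under 0.5 px landmark
jitter the median angle error is below 3 degrees. Euler angles use the
intrinsic pitch-yaw-roll (x-y-z) convention, with roll set to 0 at the
$|yaw| = 90°$ singularity — far outside the poses that occur here. Nods are
pitch excursions and tilts roll excursions; `abnormal_posture()` flags
magnitudes beyond 20° (configurable).

In `extract_features()` the same Gauss-Newton core is warm-started from the
previous frame's pose (with a cold restart whenever the residual exceeds
5 px), which makes per-frame tracking cheap enough that two hours of
15 fps video-equivalent run in about a minute.

## Denoising

`fft_smooth()` realizes a length-5 (default) moving average as circular
convolution in the frequency domain, after reflecting `(window-1)/2`
samples at each edge so that the output has the input's length, no phase
shift, and exact DC preservation. Window 5 at 15 fps spans 1/3 s — enough to
suppress landmark jitter while leaving 0.2 s blinks visible; larger windows
flatten the peaks the downstream features rely on. Smoothing is applied to
the raw feature series, per session, before factor analysis (whether the
original procedure smoothed features, scores, or both is not recoverable;
smoothing first keeps the factor model's inputs clean).

## Factor analysis

Extraction is principal-component based: columns are standardized, the
correlation matrix eigendecomposed, and per-component variance shares are
$\lambda_i/11 \times 100$ — so shares always sum to 100 and the eigenvalues
to 11, which the tests assert. The smallest `k` with cumulative share at or
above the threshold (default 95%) is retained; with the reference data's
printed shares that rule keeps six factors (a 90% rule would keep five).
Retained loadings are varimax-rotated (`stats::varimax`, Kaiser
normalization); rotation is orthogonal so per-variable communalities are
preserved, also asserted in tests. Score weights use the regression method
$W = R^{-1}\Lambda$ (with a pseudo-inverse fallback for singular $R$), so
training-table scores are exactly centred.

## Windowing and the GRNN

A fatigue judgement should rest on roughly a minute of evidence, so frames
are grouped into sliding windows of 900 frames stepped by 80 (60 s and
5.3 s at the default 15 fps). Each window becomes one sample: the
per-column mean of its factor scores, labelled by the majority of its frame
labels with ties going to fatigue (the safety-conservative side). Window
means were chosen over flattening (dimension 900k) or medians (discards
event-fraction information); the aggregation happens in `make_windows()`
and can be replaced upstream.

The classifier is Specht's generalized regression neural network: a
Nadaraya-Watson kernel average of the stored training labels,

$$\hat y(X) = \frac{\sum_i Y_i\, e^{-\lVert X-X_i\rVert^2/2\sigma^2}}
                  {\sum_i e^{-\lVert X-X_i\rVert^2/2\sigma^2}},$$

with a single bandwidth $\sigma$. Weights are computed relative to the
nearest pattern — an exact rescaling — so tiny $\sigma$ degrades to
nearest-neighbour instead of 0/0 underflow. Predictions are convex
combinations of labels; at $\sigma \to \infty$ they approach the label mean.
The decision rule is fatigue iff $\hat y \ge 0.5$, boundary inclusive.

## The genetic search for sigma

$\sigma$ is the only tuned parameter. The fitness is **leave-one-out** MSE:
with the query included in its own kernel sum, MSE $\to 0$ as
$\sigma \to 0$ for any data and the search degenerates; LOO is the standard
remedy and is computed from one precomputed pairwise-distance matrix, so
each $\sigma$ evaluation is a single `exp` pass.

The search itself is a real-coded GA: population 80, blend crossover with
probability 0.7, Gaussian mutation (sd 5% of the bound width, clipped) with
probability 0.25, tournament selection of size 3, elitism of 1, at most 200
generations over $\sigma \in (0, 2]$ (the lower bound opened by $10^{-6}$
since $\sigma = 0$ is undefined). The default stopping rule is the
generation cap, or earlier once the best fitness is at or below 0.03 and
has not improved for 25 generations; a fixed-budget `"max_only"` rule is
selectable since the literal published clause (average fitness below the
threshold *and* the cap reached) prescribes no usable early exit. Elitism
makes the best-fitness history non-increasing, which is tested, and
identical seeds reproduce identical runs.

## The synthetic simulator

`simulate_session()` generates the statistical structure the pipeline
assumes, not photorealistic faces:

* **Blinks**: cosine close/hold/open envelopes on the lid-pair distances,
  dropping below 5% of baseline. Awake blinks last 0.2-0.3 s at 15/min;
  fatigued blinks 1-2 s at 10/min. Note the *event* rate falls while the
  *closed-frame fraction* — which is what F\_blink measures — rises from
  about 4% to about 15%; long closures, not more events, are the fatigue
  signature being emulated.
* **Yawns**: 4 s mouth openings to 85% of mouth width, 2/min, fatigued only.
* **Speech**: 0.5-1.5 s modest openings (~28% of width, modulated), 2/min in
  both states — interference the yawn duration gate must reject.
* **Nods/tilts**: 20-40° pitch/roll excursions lasting 1-3 s, 3/min,
  fatigued only, on top of a small smooth attitude wander; pose landmarks
  are true pinhole projections of the generic face model under the
  per-frame rotation.
* **Jitter**: isotropic Gaussian noise (default 0.5 px) on every coordinate.

Events are scheduled as renewal processes — each start is the previous
event's end plus an exponential gap whose mean keeps the long-run start
rate at the profile rate — so empirical rates match profiles within
sampling error (tested at 3 standard errors over an hour). Uniform
placement with overlap-dropping would bias rates noticeably low once
fatigued closures occupy ~25% of the timeline.

Frame rate defaults to 15 fps so the 900-frame window spans the 60 s
observation horizon; the source procedure does not state a camera rate, so
this is a package decision. KSS labels are sampled at {1,2} awake and
{5..9} fatigued, then binarized with the `<3` / `>4` rule; 3 and 4 fall in
neither class and are excluded rather than guessed.

What the simulator does **not** emulate: illumination and occlusion
artifacts, landmark-detector failure modes (dropouts, swaps), inter-subject
variability in geometry and behaviour, gradual fatigue onset within a
session, or correlated (non-isotropic) landmark noise. Passing the
end-to-end recovery test therefore shows the pipeline's machinery is
correct and that well-separated behavioural regimes are recovered — it does
not certify accuracy on real drivers.

## The end-to-end experiment

`run_pipeline()` wires the stages together: two simulated sessions (awake
and fatigued default profiles, 2 h at 15 fps each by default), feature
extraction, per-session smoothing, one factor model over all frames
(unsupervised reduction precedes splitting, as in the reference procedure),
windowing per session, a stratified 55/20/25 train/test/validate split at
window level, GA-GRNN training on the train split, and metrics on the
validate split. Everything downstream of `(config, seed)` is deterministic,
and the stage log records timings and the chosen $\sigma$.

Two caveats are deliberate: adjacent windows overlap (900-frame windows, 80
frame step), so a random window-level split shares frames between splits —
harmless for the synthetic recovery claim, but a session-level split would
be needed for subject-generalization claims; and the positive class for
precision/recall is *normal driving*, the orientation under which the
reference confusion counts reproduce their printed headline metrics. Both
the orientation and the F1 rounding convention (precision/recall rounded to
one decimal before the F1 formula, `"round_first"`; `"exact"` available)
are explicit arguments.

Problem sizes used by the shipped tests and the acceptance script — 2 h per
class at 15 fps (216,000 frames, 2,678 windows), 100-model GRNN oracle
sweeps, 20 GA seeds, 1,000 random box pairs — were chosen as the smallest
sizes at which the statistical checks are stable.

## The improved bounding-box loss

Face detection upstream of landmark extraction regresses boxes; the
improved regression loss combines the IoU gap, the squared centre distance
normalized by the enclosing-box diagonal, and two arctan aspect-difference
penalties:

$$L = 1 - IoU + \frac{\rho^2}{c^2}
    + \frac{4}{\pi^2}\Delta^4(1 - IoU) + \frac{4}{\pi^2}\Delta^2,
  \qquad \Delta = \arctan\frac{w^{gt}}{h^{gt}} - \arctan\frac{w^{pb}}{h^{pb}}.$$

The quartic term is unusual next to the standard complete-IoU loss; it is
implemented verbatim (faithfulness over plausibility), with
`variant = "ciou"` giving the conventional $\alpha v$ form for comparison.
The loss is zero iff the boxes coincide and is translation invariant, both
fuzz-tested. `nms()` is greedy descending-score suppression with ties
broken by input order. Network training itself (the cascaded detector, its
datasets and weights) is out of scope; the geometry is what is testable at
desk scale.

## Numerical choices and degenerate inputs

* Coincident eye or mouth corners, zero calibration axes, non-finite
  coordinates, even or oversized smoothing windows, zero-variance feature
  columns (named in the error), dimension mismatches, empty windows, and
  non-rotation matrices (orthonormality checked at $10^{-6}$) all raise
  immediate errors rather than propagating NaN.
* The pose solver declares non-convergence when the RMS reprojection error
  exceeds 50 px; the tracker falls back to a cold start and, failing that,
  carries the previous frame's angles.
* GA chromosomes are clipped to bounds after mutation; fitness values must
  be finite or the offending $\sigma$ is named in the error.
* All stochastic code paths (`simulate_session()`, `ga_optimize()`, splits,
  fold assignment) take explicit integer seeds and restore the caller's RNG
  state.

## Known limitations

Single-face, single-eye landmark layout (with two eyes, compute per eye and
average); no probability calibration of the GRNN output; no per-dimension
bandwidths; the factor model assumes linear structure and the retained
dimension is threshold-driven rather than inferential; simulator realism
limits as listed above. The reference study's dataset-dependent numbers
(its GRNN accuracies, its optimal $\sigma$, its detector accuracy) depend
on private video data and are deliberately not asserted by this package's
tests.
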