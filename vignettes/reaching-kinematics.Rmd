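---
title: "Quantifying reaching kinematics and proximal compensation from 2D pose landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reaching kinematics and proximal compensation from 2D pose landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

## The problem and the measurement model

Markerless pose estimation makes it cheap to record how a person moves an
impaired arm during repetitive reaching practice: a single camera, a
full-body keypoint model, and per-frame 2D coordinates for each landmark.
The scientific question `reachkin` serves is whether improvements in hand
outcomes across practice reflect recovered arm function or proximal
compensation — trunk lean and shoulder excursion substituting for arm
extension, a pattern that is more pronounced in people with more severe
motor impairment.

The package treats a recording as a block of continuous 2D position data for
eight landmarks: the pinky finger, index finger, wrist and elbow of the
paretic arm, plus both shoulders and both hips. All kinematics are computed
in **pixels** and **pixels/second**, in image convention (origin top-left,
y increasing downward; plots flip the y axis for display). We deliberately
do not convert to millimetres: with one uncalibrated camera there is no
principled scale factor, and every downstream statistic is either
scale-equivariant (BVE, speed) or scale-free (model p-values, ICC, R²), so
pixels lose nothing.

Three derived *effectors* summarize the body per frame:

* **palm** — the centroid (arithmetic mean) of pinky, index and wrist;
* **trunk** — the centroid of the two shoulders and two hips;
* **shoulder** — the paretic-side shoulder landmark itself.

Two statistics are computed per effector and block:

* **Bivariate variable error (BVE)**, the root mean squared Euclidean
  deviation of the positions from their own centroid,
  $\mathrm{BVE} = \sqrt{\tfrac{1}{n}\sum_i \big((x_i-x_c)^2+(y_i-y_c)^2\big)}$.
  The reference point $(x_c, y_c)$ is the per-track, per-block mean position:
  BVE is the standard motor-control index of variability about the mean, and
  the $1/n$ (population) normalization is used exactly as the formula is
  conventionally written, not $1/(n-1)$. Consequently
  $\mathrm{BVE}^2 = \widehat{\sigma}^2_x + \widehat{\sigma}^2_y$ with
  population variances, and BVE is invariant to translation and rotation and
  linear in uniform rescaling. BVE is computed over the *continuous*
  position stream of a whole block, not over per-trial endpoints: with 200
  reaches per block there is no reliable per-trial segmentation in markerless
  data, and the continuous form captures both trajectory spread and
  drift of the effector over the block.
* **Mean landmark speed**, the average of framewise speeds
  $\sqrt{\Delta x^2 + \Delta y^2}\,/\,(1/\mathrm{FPS})$. The elapsed time
  between frames is taken to be exactly $1/\mathrm{FPS}$; per-sample
  timestamps are not supported. When preprocessing has dropped frames, the
  step that spans a gap does not correspond to one frame interval, so
  gap-spanning steps are excluded from the mean by default
  (`mean_speed(..., exclude_gaps = FALSE)` restores the naive mean). No
  smoothing or outlier rejection is applied before either statistic.

## Ingest and preprocessing

Recordings arrive either in the package's long CSV dialect or as raw
33-keypoint pose output (`adapt_pose33()`), which selects the eight
landmarks — resolving pinky/index/wrist/elbow to the paretic side, defined
as contralateral to the hemisphere of stroke — and converts normalized
coordinates to pixels by multiplying with the frame dimensions. Series are
assumed pre-trimmed to the task interval (an optional frame-range filter
exists on read).

Pose estimators attach a visibility confidence to each sample. Nothing in
the downstream statistics defines how to handle low-confidence samples, so
`preprocess()` makes the policy explicit and configurable: samples with
visibility below a threshold (default **0.5**) are treated as missing;
missing runs of at most `max_gap` frames (default **5**, i.e. ≤167 ms at
30 Hz, short enough that linear interpolation across a reach is a
second-order error) are filled by linear interpolation against frame index;
frames still incomplete are dropped, with interpolated/dropped counts
carried into every block summary. Preprocessing never invents frames, and a
threshold of 0 is the identity. These defaults are pragmatic, not validated
against any reference analysis — they are surfaced as arguments precisely so
a user can match their own pipeline.

## Aggregation and the analysis grid

Block summaries feed three products: a tidy per-block table; a group table
of across-participant means and **sample** SDs (n−1 — the reporting norm;
`NA` for singleton cells) for each cell of the analysis grid; and change
scores, last block of practice minus the first (default day 5 block 5 minus
day 1 block 1), joined with FMA-UE. The default grid is the 2×2 corner
design {first, last day} × {first, last block}; any grid can be requested,
but only the endpoint grid is analyzed by default since intermediate blocks
add little for a change-across-practice question at small n. Participants
missing an endpoint are reported and skipped, never silently dropped.

## The group models

Two linear mixed-effects models are fitted, one per hand outcome (palm BVE;
mean palm speed), each with the same eight fixed-effect terms — intercept,
Day, Block, trunk BVE, shoulder BVE, FMA-UE, Day×Block, trunk×shoulder BVE —
and random intercepts for **participant** and **day nested within
participant**. The two-component random structure is the variance
decomposition a repeated 2×2 design supports: stable individual differences
plus day-level session effects. Estimation is REML via `lme4`. Design
choices a user should know:

* **Factor coding**: treatment contrasts with Day 1 and Block 1 as
  reference levels. Analyses that code the contrast in the other direction
  will show the same magnitudes with flipped signs on Day/Block terms.
* **Covariates** (trunk BVE, shoulder BVE, FMA-UE) enter uncentered, and
  the interaction is the raw product; `center_covariates = TRUE` switches to
  mean-centering when the intercept should be interpretable at typical
  covariate values.
* **Inference**: Wald 95% CIs and Wald-z p-values on the fixed effects.
  With few participants these are anti-conservative relative to
  Satterthwaite or bootstrap; they are used because they are well-defined
  for every converged fit and match common mixed-model reporting. Treat
  p-values near 0.05 with care at n = 7.
* **Derived quantities**: ICC = Στ₀₀/(Στ₀₀+σ²); marginal and conditional R²
  by variance decomposition (fixed-effects variance over total; fixed plus
  random over total).
* **Degenerate fits**: incomplete rows are removed listwise with a reported
  count; a rank-deficient fixed-effects design is an error naming the
  collinear columns; a singular or non-converged fit is returned with
  `converged = FALSE` plus a warning and a banner in the text report —
  common and expected when a variance component is near zero at small n.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` exists so that every stage has inputs with known ground
truth. Each movement takes the palm from its current position to a random
target along a **minimum-jerk** profile (position fraction
$10\tau^3-15\tau^4+6\tau^5$), alternating out-and-back about a home
position; minimum jerk is the canonical point-to-point model and, being
monotone along a straight segment, makes the palm's discrete path length
exactly the sum of reach amplitudes — the basis of the analytic mean-speed
oracle `expected_mean_speed()`. That oracle reads the generator's recorded
ground truth (which stores each block's random amplitude draws) rather than
re-deriving them from the configuration, to avoid a second, duplicated RNG
path.

Compensation is modelled as coupling: the trunk translates toward the target
by `trunk_coupling` × the reach displacement, and the paretic shoulder adds
a further `shoulder_coupling` fraction on top; both fractions vary across
participants and are constructed to correlate negatively with FMA-UE,
encoding "more impairment, more proximal compensation". Because the trunk
centroid is the mean of four landmarks, the paretic shoulder's extra
excursion contributes a quarter of itself to the measured trunk path — as it
would on a real torso — and the recorded trunk ground truth is therefore
computed from the actual noise-free centroid path.

Landmarks sit at fixed body offsets from the effectors. The hand offsets sum
to zero, so the palm centroid equals the simulated palm path exactly when
noise is off. Measurement noise is isotropic Gaussian jitter applied per
rigid group: the three hand landmarks share one draw per frame (pose errors
on adjacent keypoints are strongly correlated), while elbow, shoulders and
hips jitter independently. Hence the stationary-effector BVE floors are
$\sqrt{2}\sigma$ for palm and shoulder but $\sqrt{2}\sigma/2$ for the trunk
(averaging four independent draws) — both verified by test.

Default condition values: 7 participants, 5 days × 5 blocks × 200 movements,
30 Hz, 1920×1080 frame; reach amplitude 120 ± 25 px and duration
0.8 ± 0.15 s (putting block mean palm speeds near 150–200 px/s, plausible
for seated reaching filmed at ~2 m); jitter 2 px (sub-centimetre at this
scale); trunk coupling 0.15 and shoulder coupling 0.25 (proximal BVEs an
order of magnitude below palm BVE, with shoulder > trunk); day speed gain
1.05 (a modest practice effect).

The generator is a test harness, not a biomechanical model. It does **not**
emulate joint-chain constraints, target-dependent movement times (Fitts-like
effects), fatigue or within-block drift, non-Gaussian or autocorrelated pose
error, occlusion bursts, or 3D-to-2D projection distortion. Passing tests
therefore demonstrate that the *computational pipeline* is exact and
internally consistent, and that the models recover planted effects from
data of the assumed structure — they do not validate pose-estimator accuracy
on real video.

For parameter-recovery studies the analysis table can also be simulated
directly at the summary level (`simulate_model_table()`), with known fixed
effects and variance components; the test suite uses 200 replicates of
50-participant cohorts to check unbiasedness and Wald-CI coverage, and the
closed-form jitter limit with ≈10⁵ stationary frames. These problem sizes
were chosen to pin Monte-Carlo error well below the effect sizes being
checked while keeping the suite quick to run.

## Numerical and degenerate-input choices

* CSV round trips write full double precision (15 significant digits).
* `fps` must be constant within a block; violating files are rejected.
* A track needs ≥1 point for BVE and ≥2 frames for speed; empty series,
  all-frames-dropped preprocessing, and missing metadata are named errors
  carrying the participant/day/block context.
* Interpolation is linear in the frame index and only fills interior gaps;
  boundary gaps are dropped.
* Singular-fit detection uses `lme4::isSingular` at its default tolerance.
* All randomness flows through a single integer seed in the configuration;
  identical configurations are bit-identical.

## Limitations

Single-camera 2D kinematics confound depth motion with in-plane motion;
pixel units are camera-geometry specific, so absolute BVE/speed values are
not comparable across setups (changes and model coefficients within a setup
are). Wald inference at seven participants is approximate. The package
consumes pose-estimator output and inherits its biases; it does not segment
individual reaches, compute joint angles, or produce smoothness metrics.
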