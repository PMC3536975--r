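---
title: "Decoding covert visuospatial attention in a closed loop: methods and design"
author: "covisaBCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding covert visuospatial attention in a closed loop: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covisaBCI)
```

## The problem

Covert visuospatial attention — attending to a peripheral region of the
visual field without moving the eyes — modulates activity in retinotopic
visual cortex, with left/right attention enhancing the contralateral
hemisphere and vertical attention shifting activity along the
inferior–superior axis. Because these modulations are spatially specific
and reasonably strong at high field, single fMRI volumes can be decoded
in real time and used as a brain–computer interface (BCI): the user
steers a telepresence robot by attending right, left, or up, and rests
attention at a central fixation point to do nothing.

`covisaBCI` implements that closed loop end to end in software. A
session has two phases on one continuous run of 995 volumes at
TR = 1.62 s:

* **Localizer** (270 volumes): cued attention trials of 5 TRs (8.1 s)
  each. Directional trials are randomized and always separated by a
  center trial. These volumes feed a streaming voxel-selection analysis
  and train the decoder.
* **Control** (725 volumes, 1174.5 s): every incoming volume is motion
  corrected, detrended, normalized, and classified; a directional
  classification issues a robot command (up = 50 cm forward,
  right/left = 30° turn), followed by a refractory washout.

Because no scanner is available to the package, a synthetic session
generator stands in for the magnet and the subject, with full ground
truth. Everything downstream of volume acquisition is the same code
that would face a real volume stream.

## Pipeline stages and their parameters

### Motion correction

Each volume is rigidly registered to the first localizer volume.
Both images are smoothed with a Gaussian of σ = 1 voxel before the
metric is evaluated; the similarity metric is the sum of squared
differences, minimized over 6 rigid parameters (Euler angles about the
volume center, plus translation) by 50 iterations of stochastic
gradient descent. Each iteration draws 2048 random voxels and computes
the analytic metric gradient through trilinear interpolation of the
smoothed moving image and its spatial gradient. Gains are adapted per
parameter from the accumulated squared gradients and multiplied by an
explicit decay `1/(1 + k/20)^0.602`, so the first update moves each
parameter by roughly `step0` (0.8 mm for translations, 0.015 rad for
rotations) and later updates shrink. The gain constants were chosen on
the package's noiseless phantom so that translations up to 2 voxels are
recovered to well under 0.2 voxel; all of them are exposed in
`registrationConfig()`. The corrected image is produced from the
*unsmoothed* moving image by interpolating cubic B-splines
(coefficients prefiltered with the standard recursive filter, pole
√3 − 2, mirror boundaries), so grid points are reproduced exactly under
the identity transform; voxels mapping outside the field of view are
filled with 0.

### Streaming GLM and voxel selection

During the localizer every volume performs a rank-1 update of the GLM
sufficient statistics `X'X`, `X'y`, `y'y` — nothing else is stored, so
the cost per volume is linear in the voxel count and t maps can be
produced at any time, identically to a from-scratch batch fit. The
design has five columns: the four attention regressors (boxcars
convolved with a haemodynamic kernel) and a linear drift ramp. There is
no intercept; since the attention states tile the run, the convolved
regressors sum to a constant and the baseline level lies in the design
span. To make that exact from the first volume, the convolution history
is initialized at the CENTER steady state (the subject fixates centrally
before the run starts).

At the end of the localizer, four t maps are formed with the
one-versus-rest contrasts (for right: `right − 1/3·[left + up + center]`,
drift weighted 0), using `t = w'β / sqrt((RSS/dof)·w'(X'X)⁻¹w)`.
Selection is rank-based, not threshold-based: the 500 voxels with the
highest values in each map (ties broken by lowest linear index) are
merged by set union, and connected components smaller than 5 voxels are
removed. Connectivity is face adjacency (6-neighborhood), the most
conservative standard choice; 18 and 26 are selectable. The surviving
voxels — always fewer than 2000 — are the classifier's feature space.

### Detrending and normalization

Low-frequency drift is removed with the smoothness-priors method: the
trend of a length-T series is `(I + λ²D₂'D₂)⁻¹ y`, with `D₂` the
second-difference operator and λ = 200. The regularized system is
solved by a cached Cholesky factorization, so the per-volume cost during
control is a pair of triangular solves. A perfectly linear series is
removed exactly, and λ = 0 degenerates to removing the series itself.

After the last localizer volume, the complete series of every selected
voxel is detrended in batch, and each voxel's baseline (mean) and scale
(standard deviation of the detrended series) are frozen; voxels with
zero variance cannot be normalized and are dropped from the mask.
During control, the raw (non-detrended) history is kept; each new
volume is appended, the trailing 100-volume window is re-detrended, and
the newest detrended sample is z-scored with the frozen statistics.
The support of the original online detrending is not documented, so the
window is a package choice: it is causal, has bounded cost, and
converges to batch behaviour as the window grows (this equivalence is
tested). Endpoint effects of the smoothness prior at the newest sample
are accepted as-is — an online system cannot see the future.

### Decoder

The classifier is a C-SVM with a linear kernel and C = 1, using
one-against-one multiclass decomposition: six binary SVMs, one per pair
of the four classes. Each is stored as an explicit linear decision
function (weights and bias) so classification is six dot products; the
majority class wins, and *any* tie for first place is classified as
CENTER, so the robot never acts on an ambiguous volume. The binary
problems are fit with libsvm (via e1071), whose decision-function sign
follows the order classes appear in the data; the package re-orients
each function against the fitted model's own predictions.

Training labels lag the cue by 2 volumes (≈3.24 s) to compensate
haemodynamic delay. The labeling window of the original online system
is not documented; lag 0 and a last-3-volumes-per-trial mode are
provided for sensitivity checks (`svmConfig()`). CENTER is a
first-class class: center-trial volumes are trained on like any other.

### Control state machine and robot

A directional classification emits its command and opens a 5-volume
refractory window — 1 movement volume plus 4 washout volumes (6.48 s)
with the video feedback off — during which classifications are computed
and logged but never acted on. Combined with the ~5 TRs the BOLD
response needs to become decodable, the minimum inter-command interval
is 10 TRs (16.2 s), so at most ⌊725/10⌋ = 72 commands fit in a control
phase. The 5-TR rise is a property of the simulated user and
haemodynamics, not of the state machine, which enforces only the 1+4
refractory. The control phase opens with one refractory period: the
final localizer trial is directional and its response must wash out
before the first command.

The robot moves 50 cm forward or turns ±30°; a forward move that would
cross a wall returns the robot to its pre-command pose (the physical
robot was manually reset when it locked against a wall). Optional
Gaussian jitter (σ in cm and degrees) mimics the mechanical
variability of a toy robot; it is off by default. Targets are
25 × 50 cm rectangles visited in sequence 1→2→3→4→1…, tested on the
robot's center point with closed boundaries. The published course gives
no room dimensions, so the default arena is qualitative: a 4 × 5 m room
with targets at (100, 400), (300, 400), (300, 100) and (100, 100) cm
(the start), placed so every inter-target bearing is a multiple of 30°
and every leg a multiple of 50 cm — a course the deterministic planner
can navigate exactly.

### The planner user

`runClosedLoop()` drives the control phase with a scripted user model:
at every eligible volume it attends toward the action that most reduces
the bearing error to the next target (forward when within 15°, else a
turn), returns to CENTER throughout the refractory window, and must
sustain a direction for 5 volumes before the state becomes decodable.
With the decoder bypassed (`decoder = "oracle"`), labels come from this
ground truth and the loop isolates the timing and kinematics; with
`decoder = "svm"` the full pipeline decodes simulated volumes.

## The synthetic session generator

`synthesizeSession()` emulates a 7T EPI run. Signal model per voxel:

```
value(t) = baseline · (1 + amplitude · drive(t)) + drift(t) + ε(t)
```

* **Phantom**: a brain-shaped ellipsoid of baseline 1000 (arbitrary
  scanner units) with four disjoint cuboid ROIs mirroring the
  topography of attention-modulated visual cortex at toy scale —
  right-attention ROI in the left hemisphere, left in the right,
  up placed inferiorly, center near the pole representation.
* **HRF**: canonical double-gamma (peak ≈ 5 s, undershoot ≈ 15 s)
  sampled at TR and normalized to unit sum, so `amplitude` reads as the
  fractional signal change at a sustained-attention plateau; default
  0.02 (2%, typical of attention modulation at high field). A
  pure-delay kernel is available for sensitivity checks.
* **Noise**: white Gaussian noise of sd 10 (temporal SNR ≈ 100 on
  baseline 1000, realistic for high-field EPI), per-voxel random-walk
  drift (sd 0.3/volume) plus a per-voxel linear trend (sd 5 over the
  localizer) — these exercise both the GLM drift regressor and the
  detrending stage. A zero-noise configuration reproduces the clean
  signal exactly, and the whole stream is bit-reproducible from the
  seed (per-volume RNG substreams).
* **Motion**: an optional per-volume rigid trace resamples each clean
  volume, providing ground truth for the registration stage. Off by
  default; `runClosedLoop(motionCorrect = "auto")` registers volumes
  exactly when a trace is present.

What the generator does **not** emulate: cardiac/respiratory
physiological noise, spatial autocorrelation of the noise, EPI
distortion and signal dropout, retinotopic detail of the ROI layout,
nonlinear BOLD saturation, or attention lapses of a human user. Passing
tests on this generator therefore demonstrate that the pipeline's
numerics and logic are correct under the stated signal model — not that
decoding accuracy would reach any particular level in a new human
session.

## Problem sizes and numerical choices

Tests and the acceptance script run the phantom at 24 × 24 × 12 voxels
(the full 96 × 96 × 35 acquisition matrix is supported) with the full
270-volume localizer and 725-volume control phase; this keeps a
complete closed-loop run to seconds while preserving every temporal
property of the protocol. One consequence of the smaller grid is
density: 500 selected voxels per map out of ~7000 is a far denser
selection than 500 out of ~320,000, so more noise clusters survive the
size-5 filter and the final mask (~1300 voxels) sits closer to the
2000-voxel ceiling than a full-scale selection would.

Numerical details worth knowing:

* The GLM accumulators are solved by Cholesky, falling back to a
  pseudo-inverse (with a warning) on rank-deficient designs; voxels
  with zero residual variance map to a sign-matched infinite t.
* `topVoxels()` breaks boundary ties by lowest index, making selection
  fully deterministic.
* Registration is deterministic given its seed; self-registration of
  identical volumes returns the identity exactly because the metric
  gradient vanishes.
* All world coordinates use 0-based voxel indices times the voxel
  size; NIfTI output carries an RAS+ affine built from the voxel size.

## A worked example

```{r example, eval = FALSE}
library(covisaBCI)

res <- runClosedLoop(decoder = "oracle", seed = 1)
sessionSummary(res$log)
#>   target label cumSeconds cumMovements formatted
#> 1      1     1       97.2            6    97 (6)
#> 2      2     2      210.6           13  211 (13)
#> ...
```

With the decoder bypassed, the planner reaches the four targets (and
keeps cycling) well inside the 725-volume budget, never exceeding the
72-command ceiling, with exactly 10 volumes between consecutive
commands. A full decoded run (`decoder = "svm"`) adds the simulated
volumes and the complete analysis chain.

## Known limitations

* The stochastic registration handles the small, smooth head motion it
  was designed for; it has no multi-resolution pyramid and will not
  recover large rotations.
* Streaming detrending re-solves a trailing window rather than the
  full growing history; the two agree once the window covers the
  history, but early control volumes see a shorter support.
* The planner user is deterministic and greedy; it does not model
  human attention lapses, decoding hesitation, or exploratory
  behaviour, so closed-loop target times are best-case for a given
  decoder accuracy.
* Leave-trial-out localizer accuracy on the default synthetic sessions
  (~70–75%) is in the range that makes closed-loop control workable,
  but the simulator's noise model is optimistic about temporal
  independence.
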