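# covisaBCI

Closed-loop real-time fMRI brain–computer interfacing based on covert
visuospatial attention, implemented end to end in R.

A user in the scanner fixates a central point and covertly attends
right, left, or up; the attention state modulates retinotopic visual
cortex and is decoded from every incoming volume (TR = 1.62 s) to steer
a telepresence robot — up moves 50 cm forward, right/left turn 30°,
center does nothing. A session is one continuous 995-volume run: a
270-volume localizer with cued 5-TR attention trials, then a 725-volume
control phase in which each decoded volume may issue a command.

The package implements the complete online analysis chain and, since it
ships no scanner, a synthetic session generator with ground truth:

* **Session simulator** — brain-shaped phantom with direction-tuned
  ROIs, double-gamma haemodynamics, drift, white noise, optional rigid
  head motion; bit-reproducible from a seed
  (`synthesizeSession()`, `defaultPhantom()`, `buildCueSchedule()`).
* **Motion correction** — rigid registration to the first localizer
  volume: Gaussian smoothing (σ = 1 voxel), sum-of-squared-differences
  metric, 50 iterations of stochastic gradient descent, cubic B-spline
  resampling (`registerVolume()`, `resampleVolume()`).
* **Streaming GLM** — per-voxel sufficient statistics updated with
  every volume; five regressors (right/left/up/center + linear drift);
  four one-versus-rest contrast t maps,
  t = w′β / √((RSS/dof)·w′(X′X)⁻¹w)
  (`glmState()`, `glmUpdate()`, `tMap()`, `standardContrasts()`).
* **Feature selection** — merge the 500 highest-t voxels of each map,
  drop connected clusters smaller than 5 voxels (6-connectivity); the
  surviving mask (< 2000 voxels) is the decoder's feature space
  (`selectFeatures()`, `topVoxels()`, `removeSmallClusters()`).
* **Detrending & normalization** — smoothness-priors detrending,
  trend = (I + λ²D₂′D₂)⁻¹ y with λ = 200, then per-voxel z-scoring
  frozen at the end of the localizer; causal trailing-window re-solve
  during control (`detrendBatch()`, `fitNormalizer()`,
  `processControlVolume()`).
* **Decoder** — one-against-one linear C-SVM (C = 1), six pairwise
  decision functions, majority vote, ties → CENTER
  (`trainClassifier()`, `classifyVolume()`).
* **Control loop** — refractory state machine (1 movement + 4 washout
  volumes with video off; minimum 10 TRs = 16.2 s between commands,
  at most 72 commands per session), simulated robot and target course,
  scripted planner user, full session logging
  (`controlStep()`, `executeCommand()`, `runClosedLoop()`).

## Worked example

```r
library(covisaBCI)

# Full closed-loop session on the desk-scale grid with the decoder
# bypassed by ground-truth labels (isolates timing + kinematics):
res <- runClosedLoop(decoder = "oracle", seed = 1)
sessionSummary(res$log)
#>   target label cumSeconds cumMovements formatted
#> 1      1     1       97.2            6    97 (6)
#> 2      2     2      210.6           13  211 (13)
#> 3      3     3      356.4           22  356 (22)
#> 4      4     4      469.8           29  470 (29)
#> ...continues cycling targets until the 725 volumes are up
```

The robot reaches target 1 after 97.2 s (60 volumes) using 6 commands,
and completes the four-target course after 469.8 s and 29 commands;
commands are never closer than 10 TRs apart and never exceed 72 per
session. A fully decoded run synthesizes every volume and pushes it
through the whole chain:

```r
res <- runClosedLoop(decoder = "svm", seed = 1)
length(res$mask)       # selected voxels, e.g. 1314 (< 2000)
res$log                # SessionLog: decoded class, command, pose per volume
```

A command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/covisa-bci.R simulate --config cfg.yaml --seed 1 --out session/
Rscript inst/scripts/covisa-bci.R run      --config cfg.yaml --seed 1 --out run1/
Rscript inst/scripts/covisa-bci.R evaluate --log run1/ --out eval/
```

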