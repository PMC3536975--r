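#' ScanProtocol: acquisition geometry and timing
#'
#' Describes the echo-planar acquisition the pipeline expects: repetition
#' time, the number of localizer and control volumes, the matrix size,
#' voxel dimensions, and the cue-trial length. Defaults reproduce a
#' single 995-volume run (270 localizer + 725 control) at 96 x 96 x 35
#' voxels of 1.848 x 1.848 x 2 mm with TR = 1.62 s and 5-TR trials.
#'
#' @slot tr Repetition time in seconds.
#' @slot nLocalizer Number of localizer-phase volumes.
#' @slot nControl Number of control-phase volumes.
#' @slot matrixSize Integer vector of 3 voxel grid dimensions.
#' @slot voxelMm Numeric vector of 3 voxel edge lengths in mm.
#' @slot trialLen Cue-trial length in volumes.
#' @exportClass ScanProtocol
setClass("ScanProtocol",
  representation(
    tr = "numeric",
    nLocalizer = "integer",
    nControl = "integer",
    matrixSize = "integer",
    voxelMm = "numeric",
    trialLen = "integer"
  )
)

setValidity("ScanProtocol", function(object) {
  msg <- character()
  if (length(object@tr) != 1L || object@tr <= 0) {
    msg <- c(msg, "tr must be a positive scalar")
  }
  if (object@nLocalizer <= 0L || object@nControl < 0L) {
    msg <- c(msg, "volume counts must be positive")
  }
  if (length(object@matrixSize) != 3L || any(object@matrixSize <= 0L)) {
    msg <- c(msg, "matrixSize must be 3 positive integers")
  }
  if (length(object@voxelMm) != 3L || any(object@voxelMm <= 0)) {
    msg <- c(msg, "voxelMm must be 3 positive lengths")
  }
  if (object@trialLen <= 0L || object@nLocalizer %% object@trialLen != 0L) {
    msg <- c(msg, "nLocalizer must be divisible by trialLen")
  }
  if (length(msg)) msg else TRUE
})

#' CueSchedule: the localizer cue sequence
#'
#' An ordered set of attention trials tiling the localizer phase. Every
#' directional (RIGHT/LEFT/UP) trial is separated from the next by a
#' CENTER trial.
#'
#' @slot trials data.frame with columns `direction`, `start` (first
#'   volume of the trial, 1-based), `length` (volumes).
#' @slot nVolumes Total localizer volumes covered.
#' @exportClass CueSchedule
setClass("CueSchedule",
  representation(trials = "data.frame", nVolumes = "integer")
)

setValidity("CueSchedule", function(object) {
  tr <- object@trials
  msg <- character()
  if (!all(c("direction", "start", "length") %in% names(tr))) {
    return("trials must have columns direction, start, length")
  }
  if (!all(tr$direction %in% DIRECTIONS)) {
    msg <- c(msg, "unknown direction label")
  }
  ends <- tr$start + tr$length - 1L
  if (nrow(tr) && (tr$start[1] != 1L || ends[nrow(tr)] != object@nVolumes ||
                   (nrow(tr) > 1 && any(tr$start[-1] != ends[-nrow(tr)] + 1L)))) {
    msg <- c(msg, "trials must tile the localizer phase with no gaps")
  }
  dir <- tr$direction != "CENTER"
  if (any(dir[-1] & dir[-length(dir)])) {
    msg <- c(msg, "directional trials must be separated by CENTER trials")
  }
  counts <- table(factor(tr$direction[dir], levels = setdiff(DIRECTIONS, "CENTER")))
  if (length(counts) && diff(range(counts)) > 1) {
    msg <- c(msg, "directional trial counts must be balanced to within 1")
  }
  if (length(msg)) msg else TRUE
})

#' Hrf: sampled haemodynamic impulse response
#'
#' @slot kernel Impulse response sampled at TR resolution; `kernel[1]`
#'   is the response at stimulus onset.
#' @slot lagVolumes Integer peak delay in volumes, used for labeling.
#' @exportClass Hrf
setClass("Hrf", representation(kernel = "numeric", lagVolumes = "integer"))

setValidity("Hrf", function(object) {
  s <- sum(object@kernel)
  if (!is.finite(s) || s <= 0) return("kernel must integrate to a finite positive value")
  if (object@lagVolumes < 0L) return("lagVolumes must be >= 0")
  TRUE
})

#' Phantom: synthetic brain with attention-responsive regions
#'
#' A baseline intensity volume, a brain mask, and a set of regions of
#' interest (ROIs), each responsive to one attention direction with a
#' fractional BOLD amplitude.
#'
#' @slot baseline 3D array of baseline intensities (arbitrary units).
#' @slot brainMask 3D logical array.
#' @slot rois Named list (by direction) of lists with elements `indices`
#'   (linear voxel indices) and `amplitude` (fractional signal change at
#'   sustained-attention plateau).
#' @exportClass Phantom
setClass("Phantom",
  representation(baseline = "array", brainMask = "array", rois = "list")
)

setValidity("Phantom", function(object) {
  msg <- character()
  if (!identical(dim(object@baseline), dim(object@brainMask))) {
    msg <- c(msg, "baseline and brainMask dimensions differ")
  }
  for (nm in names(object@rois)) {
    roi <- object@rois[[nm]]
    if (!nm %in% DIRECTIONS) msg <- c(msg, sprintf("unknown ROI direction '%s'", nm))
    if (roi$amplitude < 0) msg <- c(msg, "ROI amplitudes must be >= 0")
    if (any(!object@brainMask[roi$indices])) {
      msg <- c(msg, sprintf("ROI '%s' extends outside the brain mask", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' NoiseModel: stochastic components of the simulated signal
#'
#' @slot whiteSd Standard deviation of i.i.d. Gaussian noise (intensity
#'   units).
#' @slot driftRwSd Per-volume standard deviation of the random-walk
#'   drift increment.
#' @slot driftLinearSd Standard deviation, across voxels, of the total
#'   linear drift accumulated over the localizer phase.
#' @slot motionTrace Either `NULL` or an n-volume x 6 matrix of rigid
#'   parameters (3 rotations rad, 3 translations mm) applied per volume.
#' @slot seed Integer seed; the noise realization is fully determined
#'   by it.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(
    whiteSd = "numeric",
    driftRwSd = "numeric",
    driftLinearSd = "numeric",
    motionTrace = "ANY",
    seed = "integer"
  )
)

setValidity("NoiseModel", function(object) {
  if (object@whiteSd < 0 || object@driftRwSd < 0 || object@driftLinearSd < 0) {
    return("noise magnitudes must be >= 0")
  }
  if (!is.null(object@motionTrace) &&
      (!is.matrix(object@motionTrace) || ncol(object@motionTrace) != 6L)) {
    return("motionTrace must be NULL or an n x 6 matrix")
  }
  TRUE
})

#' RigidTransform: 6-parameter rigid-body transform
#'
#' Euler angles (Rz Ry Rx order) about a fixed center plus a
#' translation, acting on world (mm) coordinates where world = 0-based
#' voxel index times voxel size.
#'
#' @slot rotation 3 angles in radians.
#' @slot translation 3 offsets in mm.
#' @slot center Rotation center in mm.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric", center = "numeric")
)

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || length(object@translation) != 3L ||
      length(object@center) != 3L) {
    return("rotation, translation and center must each have length 3")
  }
  if (!all(is.finite(c(object@rotation, object@translation, object@center)))) {
    return("transform parameters must be finite")
  }
  TRUE
})

#' RegistrationConfig: rigid registration settings
#'
#' @slot sigmaVoxels Gaussian smoothing applied to both images before
#'   metric evaluation (voxels).
#' @slot iterations Stochastic gradient descent iterations.
#' @slot samplesPerIteration Voxels sampled per iteration.
#' @slot step0Mm Initial translation step scale (mm).
#' @slot step0Rad Initial rotation step scale (radians).
#' @slot gainA,gainAlpha Decaying gain sequence `1 / (1 + k/A)^alpha`.
#' @exportClass RegistrationConfig
setClass("RegistrationConfig",
  representation(
    sigmaVoxels = "numeric",
    iterations = "integer",
    samplesPerIteration = "integer",
    step0Mm = "numeric",
    step0Rad = "numeric",
    gainA = "numeric",
    gainAlpha = "numeric"
  )
)

setValidity("RegistrationConfig", function(object) {
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@sigmaVoxels < 0) return("sigmaVoxels must be >= 0")
  if (object@samplesPerIteration < 1L) return("samplesPerIteration must be >= 1")
  TRUE
})

#' GlmState: streaming GLM sufficient statistics
#'
#' Accumulates X'X, X'y and y'y so regression coefficients, residual
#' sums of squares and contrast t statistics can be recovered at any
#' point without storing the time series.
#'
#' @slot nSeen Volumes accumulated so far.
#' @slot xtx p x p design cross-product.
#' @slot xty p x V accumulator (V voxels).
#' @slot yty Length-V response sums of squares.
#' @slot regressorNames Design column names.
#' @exportClass GlmState
setClass("GlmState",
  representation(
    nSeen = "integer",
    xtx = "matrix",
    xty = "matrix",
    yty = "numeric",
    regressorNames = "character"
  )
)

setValidity("GlmState", function(object) {
  p <- length(object@regressorNames)
  if (!identical(dim(object@xtx), c(p, p))) return("xtx must be p x p")
  if (nrow(object@xty) != p) return("xty must have p rows")
  if (length(object@yty) != ncol(object@xty)) return("yty length must equal voxel count")
  if (max(abs(object@xtx - t(object@xtx))) > 1e-8 * (1 + max(abs(object@xtx)))) {
    return("xtx must be symmetric")
  }
  if (object@nSeen < 0L) return("nSeen must be >= 0")
  TRUE
})

#' Contrast: a named contrast of GLM coefficients
#'
#' @slot name Direction the contrast tests.
#' @slot weights Length-p weight vector; the drift weight is 0 and the
#'   attention weights sum to 0.
#' @exportClass Contrast
setClass("Contrast", representation(name = "character", weights = "numeric"))

#' FeatureMask: the selected voxel set
#'
#' @slot voxelIndices Sorted unique linear indices into the volume grid.
#' @slot clusterLabels Integer connected-component id per voxel.
#' @slot source Named list mapping each contributing t map to the voxel
#'   indices it proposed (before merging/cleaning).
#' @slot dims Volume grid dimensions.
#' @exportClass FeatureMask
setClass("FeatureMask",
  representation(
    voxelIndices = "integer",
    clusterLabels = "integer",
    source = "list",
    dims = "integer"
  )
)

setValidity("FeatureMask", function(object) {
  idx <- object@voxelIndices
  if (is.unsorted(idx, strictly = TRUE)) return("voxelIndices must be unique and sorted")
  if (length(idx) != length(object@clusterLabels)) {
    return("clusterLabels must align with voxelIndices")
  }
  if (length(idx) && (min(idx) < 1L || max(idx) > prod(object@dims))) {
    return("voxel indices outside the grid")
  }
  TRUE
})

#' DetrendConfig: smoothness-priors detrending settings
#'
#' @slot lambda Regularization parameter of the second-difference prior
#'   (default 200).
#' @slot controlWindow Trailing history length (volumes) used when
#'   detrending streaming control-phase samples.
#' @exportClass DetrendConfig
setClass("DetrendConfig",
  representation(lambda = "numeric", controlWindow = "integer")
)

setValidity("DetrendConfig", function(object) {
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@controlWindow < 10L) return("controlWindow must be >= 10")
  TRUE
})

#' VoxelNormalizer: frozen per-voxel baseline and scale
#'
#' Fitted on batch-detrended localizer series; during control, raw
#' values are appended to the kept history, the trailing window is
#' re-detrended, and the newest detrended sample is z-scored with the
#' frozen statistics.
#'
#' @slot baseline Per-voxel mean of the detrended localizer series.
#' @slot scale Per-voxel standard deviation of the detrended localizer
#'   series (all > 0).
#' @slot rawHistory Preallocated T x V matrix of original raw values.
#' @slot nSeen Rows of `rawHistory` filled so far.
#' @slot config The `DetrendConfig` used at fit time.
#' @exportClass VoxelNormalizer
setClass("VoxelNormalizer",
  representation(
    baseline = "numeric",
    scale = "numeric",
    rawHistory = "matrix",
    nSeen = "integer",
    config = "DetrendConfig"
  )
)

setValidity("VoxelNormalizer", function(object) {
  if (any(object@scale <= 0)) return("scale must be > 0 for every voxel")
  if (length(object@baseline) != length(object@scale) ||
      ncol(object@rawHistory) != length(object@scale)) {
    return("baseline/scale/rawHistory voxel counts differ")
  }
  TRUE
})

#' SvmConfig: decoder settings
#'
#' @slot cParam Soft-margin penalty C of the linear C-SVM (default 1).
#' @slot labelLag Volumes by which training labels lag the cue, to
#'   compensate haemodynamic delay (default 2).
#' @slot labelMode `"all"` labels every localizer volume; `"late3"`
#'   keeps only the last 3 volumes of each trial.
#' @exportClass SvmConfig
setClass("SvmConfig",
  representation(cParam = "numeric", labelLag = "integer", labelMode = "character")
)

setValidity("SvmConfig", function(object) {
  if (object@cParam <= 0) return("cParam must be > 0")
  if (!object@labelMode %in% c("all", "late3")) return("labelMode must be 'all' or 'late3'")
  if (object@labelLag < 0L) return("labelLag must be >= 0")
  TRUE
})

#' AttnClassifier: one-against-one linear SVM decoder
#'
#' Six binary linear decision functions, one per unordered pair of the
#' four attention classes. Classification is by majority vote with any
#' first-place tie resolved to CENTER.
#'
#' @slot pairs List of 6 lists with elements `classA`, `classB`,
#'   `weights`, `bias`; decision value w.x + b > 0 votes for `classA`.
#' @slot classes The four class labels.
#' @slot featureDim Feature-vector dimension (mask size).
#' @exportClass AttnClassifier
setClass("AttnClassifier",
  representation(pairs = "list", classes = "character", featureDim = "integer")
)

setValidity("AttnClassifier", function(object) {
  if (length(object@pairs) != choose(length(object@classes), 2)) {
    return("need one binary classifier per unordered class pair")
  }
  for (p in object@pairs) {
    if (length(p$weights) != object@featureDim) {
      return("weight dimension must equal featureDim for every pair")
    }
  }
  TRUE
})

#' RobotPose: planar robot pose
#'
#' @slot x,y Position in cm.
#' @slot heading Heading in degrees, counterclockwise, 0 = +x axis,
#'   normalized to [0, 360).
#' @exportClass RobotPose
setClass("RobotPose", representation(x = "numeric", y = "numeric", heading = "numeric"))

setValidity("RobotPose", function(object) {
  if (object@heading < 0 || object@heading >= 360) return("heading must be in [0, 360)")
  TRUE
})

#' Arena: the robot's room and target course
#'
#' @slot bounds Named numeric vector xmin/xmax/ymin/ymax (cm).
#' @slot targets data.frame with columns `label`, `cx`, `cy`, `w`, `h`
#'   (axis-aligned rectangles, cm; 25 x 50 by default).
#' @slot startPose `RobotPose` at the start of the control phase (at
#'   target four).
#' @exportClass Arena
setClass("Arena",
  representation(bounds = "numeric", targets = "data.frame", startPose = "RobotPose")
)

setValidity("Arena", function(object) {
  b <- object@bounds
  if (!all(c("xmin", "xmax", "ymin", "ymax") %in% names(b))) {
    return("bounds must name xmin/xmax/ymin/ymax")
  }
  t <- object@targets
  if (any(t$cx - t$w / 2 < b["xmin"] | t$cx + t$w / 2 > b["xmax"] |
          t$cy - t$h / 2 < b["ymin"] | t$cy + t$h / 2 > b["ymax"])) {
    return("targets must lie inside bounds")
  }
  TRUE
})

#' ControlState: refractory decoder state machine
#'
#' @slot refractoryRemaining Volumes left in the post-command window
#'   (1 movement volume + 4 washout volumes; 0 when idle).
#' @slot videoOn FALSE exactly during the 4 washout volumes.
#' @slot commandsIssued Commands emitted so far.
#' @slot volumeIndex Current control-phase volume (1-based).
#' @exportClass ControlState
setClass("ControlState",
  representation(
    refractoryRemaining = "integer",
    videoOn = "logical",
    commandsIssued = "integer",
    volumeIndex = "integer"
  )
)

setValidity("ControlState", function(object) {
  if (object@refractoryRemaining < 0L) return("refractoryRemaining must be >= 0")
  wash <- object@refractoryRemaining >= 1L && object@refractoryRemaining <= 4L
  if (object@videoOn == wash) return("videoOn must be FALSE iff within the 4-volume washout")
  TRUE
})

#' SessionLog: per-volume record of a closed-loop session
#'
#' @slot records data.frame, one row per control volume: `volume`,
#'   `trueState`, `decoded`, `command`, `refractory`, `videoOn`, `x`,
#'   `y`, `heading`.
#' @slot targetLog data.frame of targets reached in sequence: `target`,
#'   `cumSeconds`, `cumMovements`.
#' @slot arena The `Arena` used.
#' @slot protocol The `ScanProtocol` used.
#' @exportClass SessionLog
setClass("SessionLog",
  representation(
    records = "data.frame",
    targetLog = "data.frame",
    arena = "Arena",
    protocol = "ScanProtocol"
  )
)

#' BciSession: a synthesized 4D session with ground truth
#'
#' @slot volumes 4D array (x, y, z, volume).
#' @slot states Character vector of true attention states per volume.
#' @slot schedule The localizer `CueSchedule`.
#' @slot protocol The `ScanProtocol`.
#' @slot transformsTrue Either `NULL` or an n x 6 matrix of true rigid
#'   motion parameters per volume.
#' @exportClass BciSession
setClass("BciSession",
  representation(
    volumes = "array",
    states = "character",
    schedule = "CueSchedule",
    protocol = "ScanProtocol",
    transformsTrue = "ANY"
  )
)
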