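#' Default synthetic phantom with direction-tuned ROIs
#'
#' Builds a brain-shaped ellipsoid of uniform baseline intensity with
#' four disjoint cuboid regions that respond to one attention direction
#' each. Placement mirrors the retinotopic organisation of
#' attention-modulated visual cortex at toy scale: the RIGHT-attention
#' ROI sits in the left hemisphere (contralateral), LEFT in the right
#' hemisphere, UP inferiorly, and CENTER near the occipital pole
#' representation.
#'
#' @param matrixSize 3 integer grid dimensions. Tests and the shipped
#'   defaults use 24 x 24 x 12 for speed; the full 96 x 96 x 35
#'   acquisition matrix is supported.
#' @param baselineValue Baseline intensity inside the brain (arbitrary
#'   scanner units, default 1000).
#' @param amplitude Fractional signal change at sustained-attention
#'   plateau for every ROI (default 0.02, i.e. 2%).
#' @param roiFrac Fractional ROI edge length relative to the grid.
#' @return A [Phantom-class].
#' @examples
#' ph <- defaultPhantom(c(24, 24, 12))
#' lengths(lapply(roiIndices(ph), identity))
#' @export
defaultPhantom <- function(matrixSize = c(24L, 24L, 12L), baselineValue = 1000,
                           amplitude = 0.02, roiFrac = c(1 / 6, 1 / 6, 1 / 4)) {
  dims <- as.integer(matrixSize)
  ctr <- (dims + 1) / 2
  semi <- 0.45 * dims
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  r2 <- ((ijk[, 1] - ctr[1]) / semi[1])^2 + ((ijk[, 2] - ctr[2]) / semi[2])^2 +
    ((ijk[, 3] - ctr[3]) / semi[3])^2
  mask <- array(r2 <= 1, dim = dims)
  baseline <- array(0, dim = dims)
  baseline[mask] <- baselineValue

  roiSize <- pmax(2L, as.integer(round(dims * roiFrac)))
  centers <- list(
    RIGHT = c(0.27, 0.33, 0.50),   # left hemisphere, contralateral
    LEFT = c(0.73, 0.33, 0.50),
    UP = c(0.50, 0.42, 0.33),      # inferior visual cortex
    CENTER = c(0.50, 0.62, 0.58)
  )
  rois <- lapply(centers, function(fr) {
    c0 <- round(fr * dims)
    lo <- pmax(1L, as.integer(c0 - roiSize %/% 2L))
    hi <- pmin(dims, as.integer(lo + roiSize - 1L))
    grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
    idx <- ijkToLinear(grid, dims)
    list(indices = idx[mask[idx]], amplitude = amplitude)
  })
  new("Phantom", baseline = baseline, brainMask = mask, rois = rois)
}

#' @rdname defaultPhantom
#' @param x A `Phantom`.
#' @export
setGeneric("roiIndices", function(x) standardGeneric("roiIndices"))

#' @rdname defaultPhantom
#' @export
setMethod("roiIndices", "Phantom", function(x) {
  lapply(x@rois, function(r) r$indices)
})

#' @rdname defaultPhantom
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname defaultPhantom
#' @export
setMethod("brainMask", "Phantom", function(x) x@brainMask)

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %s grid, %d brain voxels, %d ROIs (%s)\n",
              paste(dim(object@baseline), collapse = " x "),
              sum(object@brainMask), length(object@rois),
              paste(sprintf("%s:%d", names(object@rois),
                            vapply(object@rois, function(r) length(r$indices), 0L)),
                    collapse = ", ")))
})

#' Construct a NoiseModel
#'
#' Default magnitudes emulate a high-field EPI time series with temporal
#' SNR near 100 (white noise sd 10 on a baseline of 1000), slow
#' scanner/physiological drift as a per-voxel random walk plus a linear
#' trend, and no head motion.
#'
#' @param whiteSd Gaussian noise standard deviation (intensity units).
#' @param driftRwSd Random-walk increment sd per volume.
#' @param driftLinearSd Across-voxel sd of the total linear drift
#'   accumulated over the localizer phase.
#' @param motionTrace `NULL`, or an n x 6 matrix of per-volume rigid
#'   parameters (3 rotations in radians, 3 translations in mm).
#' @param seed Integer seed fully determining the realization.
#' @return A [NoiseModel-class].
#' @export
noiseModel <- function(whiteSd = 10, driftRwSd = 0.3, driftLinearSd = 5,
                       motionTrace = NULL, seed = 1L) {
  new("NoiseModel",
      whiteSd = whiteSd, driftRwSd = driftRwSd, driftLinearSd = driftLinearSd,
      motionTrace = motionTrace, seed = as.integer(seed))
}

#' A noise-free NoiseModel
#' @param seed Integer seed (unused when all magnitudes are zero, kept
#'   for interface symmetry).
#' @return A [NoiseModel-class] with every magnitude zero.
#' @export
noiselessModel <- function(seed = 1L) {
  noiseModel(whiteSd = 0, driftRwSd = 0, driftLinearSd = 0,
             motionTrace = NULL, seed = seed)
}
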