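#' Construct registration settings
#'
#' @param sigmaVoxels Gaussian smoothing (voxels) applied to both
#'   images before the similarity metric is evaluated (default 1).
#' @param iterations Stochastic gradient descent iterations
#'   (default 50).
#' @param samplesPerIteration Random voxel samples drawn per iteration
#'   (default 2048).
#' @param step0Mm,step0Rad Initial step magnitudes for translations and
#'   rotations; per-parameter gains are adapted from the first
#'   iteration's gradient so the first update moves about this much.
#' @param gainA,gainAlpha The decaying gain sequence
#'   `step0 / (1 + k/gainA)^gainAlpha`.
#' @return A [RegistrationConfig-class].
#' @export
registrationConfig <- function(sigmaVoxels = 1, iterations = 50L,
                               samplesPerIteration = 2048L,
                               step0Mm = 0.8, step0Rad = 0.015,
                               gainA = 20, gainAlpha = 0.602) {
  new("RegistrationConfig",
      sigmaVoxels = sigmaVoxels, iterations = as.integer(iterations),
      samplesPerIteration = as.integer(samplesPerIteration),
      step0Mm = step0Mm, step0Rad = step0Rad,
      gainA = gainA, gainAlpha = gainAlpha)
}

#' Rigidly register a volume to a template
#'
#' Minimizes the sum of squared differences between the Gaussian-
#' smoothed moving and template images over 6 rigid parameters by
#' stochastic gradient descent: each iteration draws a random voxel
#' subsample, evaluates the metric gradient analytically (image
#' gradient by central differences, chain rule through the transform),
#' and takes a decaying-gain step. Rotation is parameterized as Euler
#' angles about the volume center.
#'
#' @param moving,template 3D arrays on the same grid.
#' @param voxelMm Voxel size in mm.
#' @param config A [RegistrationConfig-class].
#' @param seed Integer seed for the voxel subsampling; the result is
#'   deterministic given `(moving, template, config, seed)`.
#' @return A [RigidTransform-class] mapping template world coordinates
#'   to moving-image world coordinates.
#' @examples
#' vol <- defaultPhantom(c(12, 12, 8))@baseline
#' tf <- registerVolume(vol, vol, voxelMm = c(2, 2, 2))
#' max(abs(transformParameters(tf)))  # ~0
#' @export
registerVolume <- function(moving, template, voxelMm = c(1, 1, 1),
                           config = registrationConfig(), seed = 1L) {
  stopifnot(identical(dim(moving), dim(template)))
  if (max(template) - min(template) <= 0) {
    stop("template is constant; registration is degenerate", call. = FALSE)
  }
  dims <- dim(template)
  ctr <- worldCenter(dims, voxelMm)
  tmpS <- gaussianSmooth3d(template, config@sigmaVoxels)
  movS <- gaussianSmooth3d(moving, config@sigmaVoxels)
  # smoothed moving-image gradient (per mm), central differences
  grad <- imageGradient(movS, voxelMm)

  # candidate sample positions: interior voxels, 0-based ijk
  margin <- 2L
  lo <- rep(margin, 3)
  hi <- dims - 1L - margin
  if (any(hi < lo)) { lo <- rep(0L, 3); hi <- dims - 1L }

  params <- numeric(6)  # (rx, ry, rz, tx, ty, tz)
  gradAccum <- numeric(6)
  step0 <- c(rep(config@step0Rad, 3), rep(config@step0Mm, 3))
  withSeed(seed, {
    for (k in seq_len(config@iterations)) {
      ijk <- cbind(floor(runif(config@samplesPerIteration, lo[1], hi[1] + 1)),
                   floor(runif(config@samplesPerIteration, lo[2], hi[2] + 1)),
                   floor(runif(config@samplesPerIteration, lo[3], hi[3] + 1)))
      world <- sweep(ijk, 2, voxelMm, "*")
      tf <- rigidTransform(params[1:3], params[4:6], center = ctr)
      mapped <- applyTransform(tf, world)
      mappedVox <- sweep(mapped, 2, voxelMm, "/")
      mval <- interpolateLinear(movS, mappedVox, outValue = NA_real_)
      tval <- tmpS[ijk + 1L]
      ok <- !is.na(mval)
      if (sum(ok) < 8L) next
      r <- mval[ok] - tval[ok]
      gval <- cbind(interpolateLinear(grad[[1]], mappedVox, NA_real_),
                    interpolateLinear(grad[[2]], mappedVox, NA_real_),
                    interpolateLinear(grad[[3]], mappedVox, NA_real_))[ok, , drop = FALSE]
      dR <- rotationMatrixGrad(params[1:3])
      centered <- sweep(world[ok, , drop = FALSE], 2, ctr)
      g <- numeric(6)
      for (a in 1:3) {
        dpos <- centered %*% t(dR[[a]])
        g[a] <- mean(2 * r * rowSums(gval * dpos))
      }
      g[4:6] <- colMeans(2 * r * gval)
      # per-parameter adaptive gain: the accumulated squared gradient
      # normalizes curvature differences between parameters, and the
      # explicit 1/(1 + k/A)^alpha factor enforces a decaying gain; the
      # first update moves each parameter by about step0
      gradAccum <- gradAccum + g^2
      step <- step0 * g / sqrt(gradAccum + 1e-300) /
        (1 + (k - 1) / config@gainA)^config@gainAlpha
      params <- params - step
    }
  })
  rigidTransform(params[1:3], params[4:6], center = ctr)
}

imageGradient <- function(vol, voxelMm) {
  dims <- dim(vol)
  lapply(1:3, function(axis) {
    n <- dims[axis]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * voxelMm[axis]
    d <- switch(axis,
                (vol[ip, , , drop = FALSE] - vol[im, , , drop = FALSE]) /
                  array(denom, dims),
                (vol[, ip, , drop = FALSE] - vol[, im, , drop = FALSE]) /
                  aperm(array(denom, dims[c(2, 1, 3)]), c(2, 1, 3)),
                (vol[, , ip, drop = FALSE] - vol[, , im, drop = FALSE]) /
                  aperm(array(denom, dims[c(3, 1, 2)]), c(2, 3, 1)))
    d
  })
}

# mean squared difference between smoothed images under a transform,
# evaluated on the full interior grid (used by tests/diagnostics)
smoothedSsd <- function(moving, template, transform, voxelMm = c(1, 1, 1),
                        sigmaVoxels = 1) {
  dims <- dim(template)
  tmpS <- gaussianSmooth3d(template, sigmaVoxels)
  movS <- gaussianSmooth3d(moving, sigmaVoxels)
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- sweep(ijk, 2, voxelMm, "*")
  mapped <- sweep(applyTransform(transform, world), 2, voxelMm, "/")
  mval <- interpolateLinear(movS, mapped, outValue = NA_real_)
  ok <- !is.na(mval)
  mean((mval[ok] - tmpS[ijk[ok, , drop = FALSE] + 1L])^2)
}

#' Resample a volume under a rigid transform
#'
#' Produces the motion-corrected image on the template grid: the output
#' value at grid point x is the moving image sampled at T(x).
#' Interpolation is the interpolating cubic B-spline (coefficients
#' prefiltered so that grid points are reproduced exactly under the
#' identity transform); voxels mapping outside the field of view are
#' filled with 0.
#'
#' @param volume 3D array.
#' @param transform A [RigidTransform-class].
#' @param voxelMm Voxel size in mm.
#' @param interpolation `"bspline"` (default) or `"linear"`.
#' @return The resampled 3D array.
#' @export
resampleVolume <- function(volume, transform, voxelMm = c(1, 1, 1),
                           interpolation = c("bspline", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(all(is.finite(transformParameters(transform))))
  dims <- dim(volume)
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- sweep(ijk, 2, voxelMm, "*")
  mapped <- sweep(applyTransform(transform, world), 2, voxelMm, "/")
  vals <- if (interpolation == "bspline") {
    interpolateBspline(bsplineCoefficients(volume), mapped, outValue = 0)
  } else {
    interpolateLinear(volume, mapped, outValue = 0)
  }
  array(vals, dims)
}
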