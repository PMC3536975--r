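# Synthetic BOLD session generation.
#
# Each voxel's clean signal is baseline * (1 + amplitude * drive), where
# drive is the attention boxcar of the voxel's ROI direction convolved
# with the HRF kernel. Drift (random walk + linear) and white noise are
# added on top, and the volume is optionally resampled under a rigid
# motion trace. Per-volume RNG substreams make the stream reproducible
# bit-for-bit from the master seed.

# streaming generator used by both synthesizeSession and runClosedLoop;
# volumes must be requested in acquisition order
makeSessionGenerator <- function(protocol, phantom, hrf, noise) {
  dims <- dim(phantom@baseline)
  if (!identical(dims, as.integer(protocol@matrixSize))) {
    stop("phantom grid does not match the protocol matrix", call. = FALSE)
  }
  nTotal <- nVolumes(protocol)
  kernel <- hrfKernel(hrf)
  klen <- length(kernel)
  baselineVec <- as.numeric(phantom@baseline)
  nVox <- length(baselineVec)
  rois <- phantom@rois

  stochastic <- noise@whiteSd > 0 || noise@driftRwSd > 0 || noise@driftLinearSd > 0
  volSeeds <- if (stochastic) {
    withSeed(noise@seed, sample.int(.Machine$integer.max - 1L, nTotal))
  } else {
    integer(nTotal)
  }
  slope <- if (noise@driftLinearSd > 0) {
    withSeed(noise@seed + 1L,
             rnorm(nVox, 0, noise@driftLinearSd / max(1L, protocol@nLocalizer)))
  } else {
    numeric(nVox)
  }
  mt <- noise@motionTrace
  if (!is.null(mt) && nrow(mt) < nTotal) {
    stop("motionTrace must cover every volume", call. = FALSE)
  }

  env <- new.env(parent = emptyenv())
  env$t <- 0L
  env$walk <- numeric(nVox)
  # pre-run haemodynamic state: the subject attends CENTER before the
  # first volume, so the CENTER response starts at steady state
  env$history <- matrix(rep(as.numeric(DIRECTIONS == "CENTER"), each = klen),
                        nrow = klen, dimnames = list(NULL, DIRECTIONS))

  nextVolume <- function(state) {
    if (!state %in% DIRECTIONS) stop("unknown attention state: ", state, call. = FALSE)
    env$t <- env$t + 1L
    if (env$t > nTotal) stop("generator exhausted", call. = FALSE)
    # newest boxcar sample on top of the rolling history
    env$history <- rbind(as.numeric(DIRECTIONS == state), env$history[-klen, , drop = FALSE])
    drive <- as.numeric(kernel %*% env$history)
    names(drive) <- DIRECTIONS

    vox <- baselineVec
    for (nm in names(rois)) {
      roi <- rois[[nm]]
      if (drive[nm] != 0 && length(roi$indices)) {
        vox[roi$indices] <- vox[roi$indices] +
          baselineVec[roi$indices] * roi$amplitude * drive[nm]
      }
    }
    if (stochastic) {
      withSeed(volSeeds[env$t], {
        if (noise@driftRwSd > 0) env$walk <- env$walk + rnorm(nVox, 0, noise@driftRwSd)
        if (noise@whiteSd > 0) vox <- vox + rnorm(nVox, 0, noise@whiteSd)
      })
      vox <- vox + env$walk + slope * (env$t - 1L)
    }
    vol <- array(vox, dim = dims)
    trueTransform <- NULL
    if (!is.null(mt)) {
      p <- mt[env$t, ]
      if (any(p != 0)) {
        tf <- rigidTransform(rotation = p[1:3], translation = p[4:6],
                             center = worldCenter(dims, protocol@voxelMm))
        vol <- resampleVolume(vol, tf, voxelMm = protocol@voxelMm,
                              interpolation = "linear")
      }
      trueTransform <- p
    }
    list(volume = vol, transform = trueTransform)
  }
  list(nextVolume = nextVolume, nTotal = nTotal, dims = dims)
}

#' Synthesize a complete BCI session with ground truth
#'
#' Generates the full 4D volume stream for a session: the localizer
#' phase follows the cue schedule, the control phase follows a scripted
#' per-volume attention state. The return value carries the true
#' attention state and (when motion is injected) the true rigid
#' transform of every volume.
#'
#' @param protocol A [ScanProtocol-class].
#' @param schedule A [CueSchedule-class] covering the localizer phase.
#' @param phantom A [Phantom-class] on the protocol's grid.
#' @param hrf An [Hrf-class].
#' @param noise A [NoiseModel-class].
#' @param controlScript Character vector of length `nControl` giving the
#'   scripted attention state per control volume; defaults to all
#'   CENTER.
#' @return A [BciSession-class].
#' @examples
#' p <- scanProtocol(nLocalizer = 20L, nControl = 0L, matrixSize = c(8, 8, 4))
#' ses <- synthesizeSession(p, buildCueSchedule(p, 1), defaultPhantom(c(8, 8, 4)),
#'                          canonicalHrf(), noiselessModel())
#' dim(sessionVolumes(ses))
#' @export
synthesizeSession <- function(protocol, schedule, phantom, hrf,
                              noise = noiseModel(), controlScript = NULL) {
  stopifnot(is(protocol, "ScanProtocol"), is(schedule, "CueSchedule"),
            is(phantom, "Phantom"), is(hrf, "Hrf"), is(noise, "NoiseModel"))
  if (schedule@nVolumes != protocol@nLocalizer) {
    stop("schedule does not cover the localizer phase", call. = FALSE)
  }
  if (is.null(controlScript)) controlScript <- rep("CENTER", protocol@nControl)
  if (length(controlScript) != protocol@nControl) {
    stop(sprintf("controlScript has %d states but the protocol has %d control volumes",
                 length(controlScript), protocol@nControl), call. = FALSE)
  }
  states <- c(scheduleStates(schedule), controlScript)
  gen <- makeSessionGenerator(protocol, phantom, hrf, noise)
  dims <- gen$dims
  vols <- array(0, dim = c(dims, gen$nTotal))
  transforms <- if (is.null(noise@motionTrace)) NULL else matrix(0, gen$nTotal, 6)
  for (t in seq_len(gen$nTotal)) {
    out <- gen$nextVolume(states[t])
    vols[, , , t] <- out$volume
    if (!is.null(transforms)) transforms[t, ] <- out$transform
  }
  new("BciSession", volumes = vols, states = states, schedule = schedule,
      protocol = protocol, transformsTrue = transforms)
}

#' @rdname synthesizeSession
#' @param x A `BciSession`.
#' @export
setGeneric("sessionVolumes", function(x) standardGeneric("sessionVolumes"))

#' @rdname synthesizeSession
#' @export
setMethod("sessionVolumes", "BciSession", function(x) x@volumes)

#' @rdname synthesizeSession
#' @export
setGeneric("trueStates", function(x) standardGeneric("trueStates"))

#' @rdname synthesizeSession
#' @export
setMethod("trueStates", "BciSession", function(x) x@states)

setMethod("show", "BciSession", function(object) {
  cat(sprintf("BciSession: %s x %d volumes (%d localizer + %d control)\n",
              paste(dim(object@volumes)[1:3], collapse = " x "),
              dim(object@volumes)[4], object@protocol@nLocalizer,
              object@protocol@nControl))
})

#' Write a session to disk
#'
#' Writes the 4D series as NIfTI plus two plain-text sidecars: a
#' tab-separated ground-truth table (volume index, true state, true
#' rigid parameters) and the cue schedule as an events file in seconds.
#'
#' @param session A [BciSession-class].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeSession <- function(session, dir) {
  stopifnot(is(session, "BciSession"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeVolume4d(session@volumes, file.path(dir, "session.nii.gz"),
                voxelMm = session@protocol@voxelMm, tr = session@protocol@tr)
  tf <- session@transformsTrue
  if (is.null(tf)) tf <- matrix(0, length(session@states), 6)
  colnames(tf) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  truth <- data.frame(volume = seq_along(session@states),
                      state = session@states, tf, check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeEvents(session@schedule, session@protocol@tr, file.path(dir, "events.tsv"))
  invisible(dir)
}
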