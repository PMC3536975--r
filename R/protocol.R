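#' Construct a ScanProtocol
#'
#' @param tr Repetition time in seconds.
#' @param nLocalizer Localizer-phase volumes.
#' @param nControl Control-phase volumes.
#' @param matrixSize 3 integer grid dimensions.
#' @param voxelMm 3 voxel edge lengths in mm.
#' @param trialLen Cue-trial length in volumes.
#' @return A [ScanProtocol-class] object.
#' @examples
#' p <- scanProtocol()
#' nVolumes(p)
#' @export
scanProtocol <- function(tr = 1.62, nLocalizer = 270L, nControl = 725L,
                         matrixSize = c(96L, 96L, 35L),
                         voxelMm = c(1.848, 1.848, 2.0),
                         trialLen = 5L) {
  new("ScanProtocol",
      tr = as.numeric(tr),
      nLocalizer = as.integer(nLocalizer),
      nControl = as.integer(nControl),
      matrixSize = as.integer(matrixSize),
      voxelMm = as.numeric(voxelMm),
      trialLen = as.integer(trialLen))
}

#' @rdname scanProtocol
#' @param object,x A `ScanProtocol`.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname scanProtocol
#' @export
setMethod("nVolumes", "ScanProtocol", function(x) x@nLocalizer + x@nControl)

#' @rdname scanProtocol
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname scanProtocol
#' @export
setMethod("repetitionTime", "ScanProtocol", function(x) x@tr)

#' @rdname scanProtocol
#' @export
setGeneric("matrixSize", function(x) standardGeneric("matrixSize"))

#' @rdname scanProtocol
#' @export
setMethod("matrixSize", "ScanProtocol", function(x) x@matrixSize)

#' @rdname scanProtocol
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname scanProtocol
#' @export
setMethod("voxelSize", "ScanProtocol", function(x) x@voxelMm)

setMethod("show", "ScanProtocol", function(object) {
  cat("ScanProtocol\n")
  cat(sprintf("  TR: %.3f s   volumes: %d localizer + %d control = %d\n",
              object@tr, object@nLocalizer, object@nControl, nVolumes(object)))
  cat(sprintf("  matrix: %s   voxel: %s mm   trial: %d volumes\n",
              paste(object@matrixSize, collapse = " x "),
              paste(format(object@voxelMm), collapse = " x "),
              object@trialLen))
})

#' Timing facts implied by a protocol and the refractory rule
#'
#' Recomputes the session's timing arithmetic from the protocol and the
#' command state machine: trial duration, washout duration, minimum
#' inter-command interval (BOLD rise + movement + washout), control
#' phase duration, and the maximum number of commands the refractory
#' timing permits.
#'
#' @param protocol A [ScanProtocol-class].
#' @param riseVolumes Volumes of sustained attention needed before a
#'   directional state is decodable (default 5).
#' @param movementVolumes Volumes occupied by the movement itself
#'   (default 1).
#' @param washoutVolumes Post-movement washout volumes with video off
#'   (default 4).
#' @return Named list: `trialSeconds`, `washoutSeconds`,
#'   `minInterCommandSeconds`, `controlPhaseSeconds`, `maxCommands`,
#'   `totalVolumes`.
#' @examples
#' timingSummary(scanProtocol())
#' @export
timingSummary <- function(protocol, riseVolumes = 5L, movementVolumes = 1L,
                          washoutVolumes = 4L) {
  stopifnot(is(protocol, "ScanProtocol"))
  tr <- protocol@tr
  cycle <- riseVolumes + movementVolumes + washoutVolumes
  list(
    trialSeconds = protocol@trialLen * tr,
    washoutSeconds = washoutVolumes * tr,
    minInterCommandSeconds = cycle * tr,
    controlPhaseSeconds = protocol@nControl * tr,
    maxCommands = as.integer(protocol@nControl %/% cycle),
    totalVolumes = as.integer(nVolumes(protocol))
  )
}

#' Brain volume occupied by a voxel selection
#'
#' @param protocol A [ScanProtocol-class] (supplies the voxel size).
#' @param nVoxels Number of selected voxels.
#' @return Volume in cubic centimetres.
#' @examples
#' maskVolumeCm3(scanProtocol(), 1236)
#' @export
maskVolumeCm3 <- function(protocol, nVoxels) {
  stopifnot(is(protocol, "ScanProtocol"))
  assertScalarNumeric(nVoxels, "nVoxels", lower = 0)
  nVoxels * prod(protocol@voxelMm) / 1000
}
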