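# NIfTI I/O, the volume-stream abstraction, and pipeline configuration.
#
# Internal voxel indexing is 0-based with (x, y, z) the
# fastest-to-slowest varying axes; the NIfTI affine is RAS+ built from
# the voxel size alone (no rotation), so world mm = index * voxelMm.

niftiAffine <- function(voxelMm) {
  a <- diag(c(voxelMm, 1))
  a
}

writeVolume4d <- function(volumes, path, voxelMm = c(1, 1, 1), tr = 1) {
  img <- RNifti::asNifti(volumes,
                         reference = list(pixdim = c(-1, voxelMm, tr, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

writeVolume3d <- function(volume, path, voxelMm = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume,
                         reference = list(pixdim = c(-1, voxelMm, 1, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Open a session as an ordered volume stream
#'
#' Abstracts the per-TR volume feed of a real-time acquisition: the
#' source is either a 4D NIfTI file on disk or a [BciSession-class] in
#' memory, and volumes are yielded strictly in acquisition order with
#' their index and timestamp (`index * TR`).
#'
#' @param source Path to a 4D NIfTI file, or a [BciSession-class].
#' @param protocol A [ScanProtocol-class]; the stream is validated
#'   against its grid and volume count.
#' @return A list with functions `hasNext()`, `nextVolume()` (returns
#'   `list(volume, index, timestamp)`), and the field `nTotal`.
#' @export
readVolumeStream <- function(source, protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  if (is(source, "BciSession")) {
    vols <- source@volumes
  } else {
    img <- RNifti::readNifti(source)
    vols <- array(as.numeric(img), dim = dim(img))
  }
  d <- dim(vols)
  if (length(d) != 4L) stop("expected a 4D volume series", call. = FALSE)
  if (!identical(as.integer(d[1:3]), protocol@matrixSize)) {
    stop(sprintf("grid %s does not match the protocol matrix %s",
                 paste(d[1:3], collapse = "x"),
                 paste(protocol@matrixSize, collapse = "x")), call. = FALSE)
  }
  if (d[4] != nVolumes(protocol)) {
    stop(sprintf("expected %d volumes but found %d",
                 nVolumes(protocol), d[4]), call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  list(
    hasNext = function() env$i < d[4],
    nextVolume = function() {
      if (env$i >= d[4]) stop("volume stream exhausted", call. = FALSE)
      env$i <- env$i + 1L
      list(volume = vols[, , , env$i], index = env$i,
           timestamp = (env$i - 1L) * protocol@tr)
    },
    nTotal = d[4]
  )
}

#' Default pipeline configuration
#'
#' A nested list mirroring every stage's settings, with defaults equal
#' to the printed online-analysis parameters: TR 1.62 s, 270 + 725
#' volumes, 5-TR trials, lambda = 200, C = 1, top-500 selection,
#' minimum cluster 5, smoothing sigma 1 voxel, 50 registration
#' iterations, 50 cm forward moves, 30 degree turns, 4-volume washout.
#'
#' @return Named nested list.
#' @export
defaultPipelineConfig <- function() {
  list(
    protocol = list(tr = 1.62, nLocalizer = 270L, nControl = 725L,
                    matrixSize = c(24L, 24L, 12L),
                    voxelMm = c(1.848, 1.848, 2.0), trialLen = 5L),
    phantom = list(baselineValue = 1000, amplitude = 0.02),
    noise = list(whiteSd = 10, driftRwSd = 0.3, driftLinearSd = 5),
    registration = list(sigmaVoxels = 1, iterations = 50L,
                        samplesPerIteration = 2048L),
    selection = list(k = 500L, minCluster = 5L, connectivity = 6L),
    detrend = list(lambda = 200, controlWindow = 100L),
    svm = list(cParam = 1, labelLag = 2L),
    control = list(riseVolumes = 5L, forwardCm = 50, turnDeg = 30,
                   washoutVolumes = 4L, jitterSdCm = 0, jitterSdDeg = 0),
    seeds = list(schedule = 1L, session = 1L)
  )
}

#' Read / write a pipeline configuration
#'
#' The configuration is stored as YAML; unknown keys are rejected so a
#' typo cannot silently fall back to a default, and a written
#' configuration reads back losslessly.
#'
#' @param path File path.
#' @param config Nested configuration list (see
#'   [defaultPipelineConfig()]); missing keys take their defaults.
#' @return `readPipelineConfig` returns the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  mergeConfig(defaultPipelineConfig(), user, path = "")
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]],
                                    path = paste0(path, nm, "."))
    } else {
      value <- user[[nm]]
      if (is.integer(defaults[[nm]])) value <- as.integer(value)
      defaults[[nm]] <- value
    }
  }
  defaults
}

configProtocol <- function(config) {
  p <- config$protocol
  scanProtocol(tr = p$tr, nLocalizer = p$nLocalizer, nControl = p$nControl,
               matrixSize = p$matrixSize, voxelMm = p$voxelMm,
               trialLen = p$trialLen)
}
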