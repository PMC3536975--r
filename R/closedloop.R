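#' Run the localizer analysis on a session
#'
#' Streams the localizer volumes through the online pipeline: optional
#' rigid motion correction to the first localizer volume, incremental
#' GLM updates with the five-regressor design, the four one-versus-rest
#' contrast t maps, top-k + cluster-size voxel selection, batch
#' detrending and normalizer fitting (voxels with zero variance are
#' dropped from the mask), and one-against-one SVM training.
#'
#' @param session A [BciSession-class] covering at least the localizer
#'   phase.
#' @param hrf An [Hrf-class] used for the design regressors.
#' @param k Top voxels per t map (default 500).
#' @param minCluster Minimum cluster size (default 5).
#' @param connectivity Cluster neighbourhood (default 6).
#' @param detrendCfg A [DetrendConfig-class].
#' @param svmCfg An [SvmConfig-class].
#' @param regCfg A [RegistrationConfig-class].
#' @param motionCorrect `"auto"` (correct iff the session carries a
#'   motion trace), `"on"` or `"off"`.
#' @param seed Integer seed (registration subsampling).
#' @return List with `mask` ([FeatureMask-class]), `tMaps`,
#'   `normalizer`, `classifier`, `trainFeatures` (normalized localizer
#'   features of the masked voxels), `schedule`, `glm`, `template`,
#'   `transforms` (per-volume estimated rigid parameters, all zero
#'   when correction is off).
#' @export
runLocalizer <- function(session, hrf = canonicalHrf(repetitionTime(session@protocol)),
                         k = 500L, minCluster = 5L, connectivity = 6L,
                         detrendCfg = detrendConfig(),
                         svmCfg = svmConfig(),
                         regCfg = registrationConfig(),
                         motionCorrect = c("auto", "on", "off"),
                         seed = 1L) {
  stopifnot(is(session, "BciSession"))
  motionCorrect <- match.arg(motionCorrect)
  doCorrect <- switch(motionCorrect,
                      auto = !is.null(session@transformsTrue),
                      on = TRUE, off = FALSE)
  protocol <- session@protocol
  dims <- dim(session@volumes)[1:3]
  nLoc <- protocol@nLocalizer
  design <- localizerDesign(session@schedule, hrf, nLoc)
  state <- glmState(prod(dims))
  template <- session@volumes[, , , 1]
  corrected <- array(0, dim = c(dims, nLoc))
  transforms <- matrix(0, nLoc, 6,
                       dimnames = list(NULL, c("rx", "ry", "rz", "tx", "ty", "tz")))
  for (t in seq_len(nLoc)) {
    vol <- session@volumes[, , , t]
    if (doCorrect && t > 1L) {
      tf <- registerVolume(vol, template, voxelMm = protocol@voxelMm,
                           config = regCfg, seed = seed + t)
      transforms[t, ] <- transformParameters(tf)
      vol <- resampleVolume(vol, tf, voxelMm = protocol@voxelMm)
    }
    corrected[, , , t] <- vol
    state <- glmUpdate(state, design[t, ], as.numeric(vol))
  }
  contrasts <- standardContrasts()
  tMaps <- lapply(contrasts, function(ct) tMap(state, ct))
  mask <- selectFeatures(tMaps, dims, k = k, minCluster = minCluster,
                         connectivity = connectivity)
  series <- matrix(aperm(corrected, c(4, 1, 2, 3)), nrow = nLoc)[, maskIndices(mask),
                                                                 drop = FALSE]
  normalizer <- fitNormalizer(series, detrendCfg,
                              nTotal = nVolumes(protocol))
  bad <- attr(normalizer, "zeroVariance")
  if (length(bad)) {
    keep <- setdiff(seq_len(length(mask)), bad)
    mask <- new("FeatureMask", voxelIndices = mask@voxelIndices[keep],
                clusterLabels = mask@clusterLabels[keep],
                source = mask@source, dims = mask@dims)
    series <- series[, keep, drop = FALSE]
    normalizer <- fitNormalizer(series, detrendCfg, nTotal = nVolumes(protocol))
  }
  trainFeatures <- normalizeSeries(normalizer)
  examples <- buildTrainingSet(session@schedule, trainFeatures, svmCfg)
  classifier <- trainClassifier(examples, svmCfg)
  list(mask = mask, tMaps = tMaps, normalizer = normalizer,
       classifier = classifier, trainFeatures = trainFeatures,
       schedule = session@schedule, glm = state, template = template,
       transforms = transforms)
}

#' Run a complete closed-loop session
#'
#' Simulates the full experiment: the localizer phase (cue schedule,
#' streaming GLM, feature selection, detrend/normalize, SVM training)
#' followed by the control phase in which a scripted planner user
#' steers its covert attention toward the action that brings the robot
#' closer to the next target. Each control volume is decoded and fed
#' through the refractory state machine; commands move the simulated
#' robot through the arena.
#'
#' The planner models the haemodynamic rise: its attention must be
#' sustained for `riseVolumes` volumes before the directional state is
#' detectable, and it returns to CENTER during the post-command
#' refractory window. Together with the 1+4 volume refractory this
#' reproduces the 10-TR minimum inter-command interval. The control
#' phase opens with one refractory period while the final localizer
#' trial's response washes out, so at most
#' `floor(nControl / 10)` commands fit in a session.
#'
#' @param protocol A [ScanProtocol-class].
#' @param phantom A [Phantom-class] on the protocol grid.
#' @param hrf An [Hrf-class].
#' @param noise A [NoiseModel-class].
#' @param arena An [Arena-class].
#' @param decoder `"svm"` runs the full decoding pipeline on simulated
#'   volumes; `"oracle"` bypasses decoding and uses the rise-aware
#'   ground-truth labels (no volumes are synthesized), isolating the
#'   control loop from decoder errors.
#' @param riseVolumes Sustained-attention volumes needed before a
#'   directional state is decodable (default 5).
#' @param scheduleSeed,seed Seeds for the cue schedule and for the
#'   run's stochastic components; the session log is identical
#'   byte-for-byte across runs with the same seeds.
#' @param jitterSdCm,jitterSdDeg Optional movement jitter (default 0).
#' @inheritParams runLocalizer
#' @return List with `log` ([SessionLog-class]), and for `"svm"` runs
#'   the localizer artifacts (`mask`, `classifier`, `normalizer`,
#'   `tMaps`).
#' @export
runClosedLoop <- function(protocol = scanProtocol(matrixSize = c(24L, 24L, 12L)),
                          phantom = defaultPhantom(matrixSize(protocol)),
                          hrf = canonicalHrf(repetitionTime(protocol)),
                          noise = noiseModel(seed = seed),
                          arena = defaultArena(),
                          decoder = c("svm", "oracle"),
                          riseVolumes = 5L,
                          k = 500L, minCluster = 5L,
                          detrendCfg = detrendConfig(),
                          svmCfg = svmConfig(),
                          regCfg = registrationConfig(),
                          motionCorrect = c("auto", "on", "off"),
                          jitterSdCm = 0, jitterSdDeg = 0,
                          scheduleSeed = seed, seed = 1L) {
  decoder <- match.arg(decoder)
  motionCorrect <- match.arg(motionCorrect)
  schedule <- buildCueSchedule(protocol, scheduleSeed)
  tr <- protocol@tr
  doCorrect <- switch(motionCorrect,
                      auto = !is.null(noise@motionTrace),
                      on = TRUE, off = FALSE)

  loc <- NULL
  gen <- NULL
  normalizer <- NULL
  template <- NULL
  if (decoder == "svm") {
    gen <- makeSessionGenerator(protocol, phantom, hrf, noise)
    locStates <- scheduleStates(schedule)
    dims <- gen$dims
    locVols <- array(0, dim = c(dims, protocol@nLocalizer))
    locTf <- if (is.null(noise@motionTrace)) NULL else matrix(0, protocol@nLocalizer, 6)
    for (t in seq_len(protocol@nLocalizer)) {
      out <- gen$nextVolume(locStates[t])
      locVols[, , , t] <- out$volume
      if (!is.null(locTf)) locTf[t, ] <- out$transform
    }
    locSession <- new("BciSession", volumes = locVols,
                      states = locStates, schedule = schedule,
                      protocol = protocol, transformsTrue = locTf)
    loc <- runLocalizer(locSession, hrf = hrf, k = k, minCluster = minCluster,
                        detrendCfg = detrendCfg, svmCfg = svmCfg,
                        regCfg = regCfg, motionCorrect = motionCorrect,
                        seed = seed)
    normalizer <- loc$normalizer
    template <- loc$template
  }

  pose <- arena@startPose
  progress <- newProgress(1L)
  # the final localizer trial's BOLD response washes out before the
  # first command can be issued
  ctl <- new("ControlState", refractoryRemaining = 5L, videoOn = TRUE,
             commandsIssued = 0L, volumeIndex = 0L)
  attendDir <- "CENTER"
  riseCount <- 0L
  nCtl <- protocol@nControl
  rec <- data.frame(
    volume = seq_len(nCtl), trueState = "CENTER", decoded = "CENTER",
    command = NA_character_, refractory = FALSE, videoOn = TRUE,
    x = numeric(nCtl), y = numeric(nCtl), heading = numeric(nCtl),
    rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0,
    stringsAsFactors = FALSE
  )
  withSeed(seed + 7L, {
    for (t in seq_len(nCtl)) {
      if (ctl@refractoryRemaining > 0L) {
        attention <- "CENTER"
        riseCount <- 0L
        attendDir <- "CENTER"
      } else {
        target <- arena@targets[arena@targets$label == progress$nextTarget, ]
        desired <- plannerAction(pose, target)
        riseCount <- if (identical(desired, attendDir)) riseCount + 1L else 1L
        attendDir <- desired
        attention <- desired
      }
      trueLabel <- if (ctl@refractoryRemaining == 0L && riseCount >= riseVolumes) {
        attendDir
      } else {
        "CENTER"
      }
      decoded <- if (decoder == "oracle") {
        trueLabel
      } else {
        out <- gen$nextVolume(attention)
        vol <- out$volume
        if (doCorrect) {
          tf <- registerVolume(vol, template, voxelMm = protocol@voxelMm,
                               config = regCfg, seed = seed + protocol@nLocalizer + t)
          rec[t, c("rx", "ry", "rz", "tx", "ty", "tz")] <-
            as.list(transformParameters(tf))
          vol <- resampleVolume(vol, tf, voxelMm = protocol@voxelMm)
        }
        pc <- processControlVolume(normalizer, vol[maskIndices(loc$mask)])
        normalizer <- pc$normalizer
        classifyVolume(loc$classifier, pc$features)
      }
      stepOut <- controlStep(ctl, decoded)
      ctl <- stepOut$state
      if (!is.na(stepOut$command)) {
        pose <- executeCommand(pose, stepOut$command, arena,
                               jitterSdCm = jitterSdCm, jitterSdDeg = jitterSdDeg)
        riseCount <- 0L
        attendDir <- "CENTER"
      }
      progress <- checkTargets(pose, arena, progress,
                               cumSeconds = t * tr,
                               cumMovements = ctl@commandsIssued)
      rec$trueState[t] <- attention
      rec$decoded[t] <- decoded
      rec$command[t] <- stepOut$command
      rec$refractory[t] <- ctl@refractoryRemaining > 0L
      rec$videoOn[t] <- ctl@videoOn
      rec$x[t] <- pose@x
      rec$y[t] <- pose@y
      rec$heading[t] <- pose@heading
    }
  })
  log <- new("SessionLog", records = rec, targetLog = progress$reached,
             arena = arena, protocol = protocol)
  out <- list(log = log)
  if (!is.null(loc)) {
    out$mask <- loc$mask
    out$classifier <- loc$classifier
    out$normalizer <- normalizer
    out$tMaps <- loc$tMaps
  }
  out
}

#' @rdname runClosedLoop
#' @param x A `SessionLog`.
#' @export
setGeneric("sessionRecords", function(x) standardGeneric("sessionRecords"))

#' @rdname runClosedLoop
#' @export
setMethod("sessionRecords", "SessionLog", function(x) x@records)

#' @rdname runClosedLoop
#' @export
setGeneric("targetsReached", function(x) standardGeneric("targetsReached"))

#' @rdname runClosedLoop
#' @export
setMethod("targetsReached", "SessionLog", function(x) x@targetLog)

setMethod("show", "SessionLog", function(object) {
  cat(sprintf("SessionLog: %d control volumes, %d commands, %d targets reached\n",
              nrow(object@records), sum(!is.na(object@records$command)),
              nrow(object@targetLog)))
})

#' Tabular session summary
#'
#' Formats the target log in the style of a performance table:
#' cumulative seconds from the start of the control phase until each
#' target, with the cumulative movement count in brackets.
#'
#' @param log A [SessionLog-class].
#' @return data.frame with columns `target`, `label`, `cumSeconds`,
#'   `cumMovements`, `formatted`.
#' @export
sessionSummary <- function(log) {
  stopifnot(is(log, "SessionLog"))
  t <- log@targetLog
  t$formatted <- sprintf("%.0f (%d)", t$cumSeconds, t$cumMovements)
  t
}

#' Write a session log to disk
#'
#' Writes the per-volume records as a tab-separated file and a plain
#' summary block (targets reached with cumulative times and movement
#' counts, command total).
#'
#' @param log A [SessionLog-class].
#' @param dir Output directory.
#' @export
writeSessionLog <- function(log, dir) {
  stopifnot(is(log, "SessionLog"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(log@records, file.path(dir, "control_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- sessionSummary(log)
  lines <- c(
    sprintf("commands issued\t%d", sum(!is.na(log@records$command))),
    sprintf("targets reached\t%d", nrow(s)),
    if (nrow(s)) sprintf("target %d\t%s", s$target, s$formatted)
  )
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Plot the robot's path
#'
#' Draws the arena, targets, and the positions after each forward
#' movement (turn-only commands do not change position).
#'
#' @param log A [SessionLog-class].
#' @param file Optional PNG path; when `NULL` draws on the current
#'   device.
#' @export
plotPath <- function(log, file = NULL) {
  stopifnot(is(log, "SessionLog"))
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 700)
    on.exit(grDevices::dev.off())
  }
  b <- log@arena@bounds
  graphics::plot(NA, xlim = b[c("xmin", "xmax")], ylim = b[c("ymin", "ymax")],
                 asp = 1, xlab = "x (cm)", ylab = "y (cm)", main = "Robot path")
  tg <- log@arena@targets
  graphics::rect(tg$cx - tg$w / 2, tg$cy - tg$h / 2,
                 tg$cx + tg$w / 2, tg$cy + tg$h / 2, border = "grey40")
  graphics::text(tg$cx, tg$cy, tg$label, col = "grey40")
  r <- log@records
  moved <- c(TRUE, diff(r$x) != 0 | diff(r$y) != 0)
  graphics::lines(r$x[moved], r$y[moved], col = "steelblue")
  graphics::points(r$x[moved], r$y[moved], pch = 16, cex = 0.6, col = "steelblue")
  invisible(log)
}
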