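#' Build a randomized localizer cue schedule
#'
#' Tiles the localizer phase with alternating CENTER and directional
#' trials, starting with CENTER, so that every RIGHT/LEFT/UP trial is
#' separated from the next by a CENTER trial. The directional labels are
#' a balanced randomized sequence: with the default protocol (270
#' localizer volumes, 5-TR trials) the schedule holds 54 trials, 27
#' CENTER and 9 of each direction.
#'
#' @param protocol A [ScanProtocol-class].
#' @param seed Integer seed; the schedule is deterministic given
#'   `(protocol, seed)`.
#' @return A [CueSchedule-class].
#' @examples
#' sched <- buildCueSchedule(scanProtocol(), seed = 1)
#' table(trials(sched)$direction)
#' @export
buildCueSchedule <- function(protocol, seed = 1L) {
  stopifnot(is(protocol, "ScanProtocol"))
  if (protocol@nLocalizer %% protocol@trialLen != 0L) {
    stop("localizer phase is not tileable by the trial length", call. = FALSE)
  }
  nTrials <- protocol@nLocalizer %/% protocol@trialLen
  nDir <- nTrials %/% 2L          # even slots (2, 4, ...) are directional
  dirs <- setdiff(DIRECTIONS, "CENTER")
  labels <- withSeed(seed, {
    base <- rep(dirs, nDir %/% length(dirs))
    extra <- if (nDir %% length(dirs) > 0) sample(dirs, nDir %% length(dirs)) else character()
    sample(c(base, extra))
  })
  direction <- rep("CENTER", nTrials)
  direction[seq_len(nTrials) %% 2L == 0L] <- labels
  trials <- data.frame(
    direction = direction,
    start = as.integer((seq_len(nTrials) - 1L) * protocol@trialLen + 1L),
    length = rep(protocol@trialLen, nTrials),
    stringsAsFactors = FALSE
  )
  new("CueSchedule", trials = trials, nVolumes = protocol@nLocalizer)
}

#' @rdname buildCueSchedule
#' @param x A `CueSchedule`.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname buildCueSchedule
#' @export
setMethod("trials", "CueSchedule", function(x) x@trials)

setMethod("show", "CueSchedule", function(object) {
  tab <- table(factor(object@trials$direction, levels = DIRECTIONS))
  cat(sprintf("CueSchedule: %d trials over %d volumes (%s)\n",
              nrow(object@trials), object@nVolumes,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

#' Per-volume attention state implied by a schedule
#'
#' @param schedule A [CueSchedule-class].
#' @return Character vector of length `nVolumes`, one state per volume.
#' @export
scheduleStates <- function(schedule) {
  stopifnot(is(schedule, "CueSchedule"))
  rep(schedule@trials$direction, schedule@trials$length)
}

#' Predicted BOLD regressors for each attention direction
#'
#' Convolves each direction's cue boxcar with the haemodynamic kernel
#' and truncates to `nVolumes`. A linear drift ramp is returned
#' alongside the four attention regressors.
#'
#' @param schedule A [CueSchedule-class] (or any per-volume state vector
#'   via `states`).
#' @param hrf An [Hrf-class].
#' @param nVolumes Series length; defaults to the schedule's coverage.
#' @param states Optional explicit per-volume state vector overriding
#'   the schedule expansion (used for control-phase scripts).
#' @return List with `regressors` (nVolumes x 4 matrix, columns RIGHT,
#'   LEFT, UP, CENTER) and `drift` (linear ramp from 0 to 1).
#' @examples
#' sched <- buildCueSchedule(scanProtocol(), seed = 1)
#' r <- attentionRegressors(sched, canonicalHrf())
#' dim(r$regressors)
#' @export
attentionRegressors <- function(schedule, hrf, nVolumes = NULL, states = NULL) {
  if (is.null(states)) {
    stopifnot(is(schedule, "CueSchedule"))
    states <- scheduleStates(schedule)
  }
  if (is.null(nVolumes)) nVolumes <- length(states)
  if (length(states) < nVolumes) {
    stop("schedule does not cover the requested number of volumes", call. = FALSE)
  }
  states <- states[seq_len(nVolumes)]
  kernel <- hrfKernel(hrf)
  # the subject attends CENTER before the run starts, so the pre-run
  # haemodynamic state is the CENTER steady state; padding the
  # convolution history accordingly makes the four regressors sum to
  # exactly sum(kernel) at every volume, so a constant baseline lies in
  # the span of the five-column design (which has no intercept)
  pad <- rep("CENTER", length(kernel))
  padded <- c(pad, states)
  reg <- vapply(DIRECTIONS, function(d) {
    full <- convolveCausal(as.numeric(padded == d), kernel)
    full[length(pad) + seq_len(nVolumes)]
  }, numeric(nVolumes))
  drift <- if (nVolumes > 1) (seq_len(nVolumes) - 1) / (nVolumes - 1) else 0
  list(regressors = reg, drift = drift)
}

#' Localizer design matrix
#'
#' The five-column design used by the streaming GLM: the four
#' HRF-convolved attention regressors plus a linear drift ramp.
#'
#' @inheritParams attentionRegressors
#' @return nVolumes x 5 matrix with columns RIGHT, LEFT, UP, CENTER,
#'   drift.
#' @export
localizerDesign <- function(schedule, hrf, nVolumes = NULL) {
  r <- attentionRegressors(schedule, hrf, nVolumes)
  cbind(r$regressors, drift = r$drift)
}

#' Write a schedule as a plain-text events table
#'
#' Tab-separated columns onset, duration (seconds) and label.
#'
#' @param schedule A [CueSchedule-class].
#' @param tr Repetition time in seconds.
#' @param path Output file path.
#' @export
writeEvents <- function(schedule, tr, path) {
  tr0 <- schedule@trials
  ev <- data.frame(
    onset = (tr0$start - 1L) * tr,
    duration = tr0$length * tr,
    label = tr0$direction
  )
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
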