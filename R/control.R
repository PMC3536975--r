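#' Construct a robot pose
#'
#' @param x,y Position in cm.
#' @param heading Heading in degrees counterclockwise, 0 = +x axis.
#' @return A [RobotPose-class].
#' @export
robotPose <- function(x = 0, y = 0, heading = 0) {
  new("RobotPose", x = x, y = y, heading = wrapHeading(heading))
}

setMethod("show", "RobotPose", function(object) {
  cat(sprintf("RobotPose: (%.1f, %.1f) cm, heading %.1f deg\n",
              object@x, object@y, object@heading))
})

#' Default arena: a 4 x 5 m room with four targets
#'
#' Four 25 x 50 cm targets laid out around the room; the robot starts
#' at target four and must visit 1, 2, 3, 4 in sequence, wrapping back
#' to 1. The default coordinates put all inter-target bearings on
#' multiples of 30 degrees so the course is exactly navigable with
#' 50 cm forward steps and 30 degree turns.
#'
#' @return An [Arena-class].
#' @export
defaultArena <- function() {
  targets <- data.frame(
    label = 1:4,
    cx = c(100, 300, 300, 100),
    cy = c(400, 400, 100, 100),
    w = 25, h = 50
  )
  new("Arena",
      bounds = c(xmin = 0, xmax = 400, ymin = 0, ymax = 500),
      targets = targets,
      startPose = robotPose(100, 100, 90))
}

setMethod("show", "Arena", function(object) {
  b <- object@bounds
  cat(sprintf("Arena: %.0f x %.0f cm, %d targets, start (%.0f, %.0f, %.0f deg)\n",
              b["xmax"] - b["xmin"], b["ymax"] - b["ymin"],
              nrow(object@targets), object@startPose@x, object@startPose@y,
              object@startPose@heading))
})

#' Initial control state
#'
#' @return A [ControlState-class] with no refractory period pending.
#' @export
controlState <- function() {
  new("ControlState", refractoryRemaining = 0L, videoOn = TRUE,
      commandsIssued = 0L, volumeIndex = 0L)
}

#' One tick of the refractory command state machine
#'
#' If a refractory period is pending, it is decremented and no command
#' is emitted regardless of the decoded class. Otherwise a directional
#' class (RIGHT/LEFT/UP) emits its mapped command (TURN_RIGHT,
#' TURN_LEFT, FORWARD) and starts a 5-volume refractory period: 1
#' movement volume followed by 4 washout volumes during which the video
#' feedback is off. CENTER never emits a command.
#'
#' @param state A [ControlState-class].
#' @param label Decoded class for this volume.
#' @return List with `command` (`NA` or a command string) and `state`
#'   (updated [ControlState-class]).
#' @export
controlStep <- function(state, label) {
  stopifnot(is(state, "ControlState"))
  if (!label %in% DIRECTIONS) stop("unknown class label: ", label, call. = FALSE)
  state@volumeIndex <- state@volumeIndex + 1L
  command <- NA_character_
  if (state@refractoryRemaining > 0L) {
    state@refractoryRemaining <- state@refractoryRemaining - 1L
  } else if (label != "CENTER") {
    command <- COMMANDS[[label]]
    state@commandsIssued <- state@commandsIssued + 1L
    state@refractoryRemaining <- 5L  # 1 movement volume + 4 washout volumes
  }
  state@videoOn <- !(state@refractoryRemaining >= 1L && state@refractoryRemaining <= 4L)
  list(command = command, state = state)
}

#' Execute a robot command
#'
#' FORWARD advances 50 cm along the heading; TURN_LEFT / TURN_RIGHT
#' rotate the heading +/-30 degrees. If a forward move would cross a
#' wall the robot is put back at its pre-command pose, mirroring the
#' manual reset used when the physical robot locked against the wall.
#' Optional Gaussian jitter (sd in cm for moves, degrees for turns)
#' mimics the mechanical variability of a toy robot.
#'
#' @param pose A [RobotPose-class] inside the arena.
#' @param command `"FORWARD"`, `"TURN_LEFT"` or `"TURN_RIGHT"` (or
#'   `NA`, returned unchanged).
#' @param arena An [Arena-class].
#' @param jitterSdCm,jitterSdDeg Optional movement noise (default 0 =
#'   off).
#' @return The new [RobotPose-class].
#' @export
executeCommand <- function(pose, command, arena, jitterSdCm = 0, jitterSdDeg = 0) {
  stopifnot(is(pose, "RobotPose"), is(arena, "Arena"))
  if (is.na(command)) return(pose)
  if (command == "FORWARD") {
    dist <- 50 + if (jitterSdCm > 0) rnorm(1, 0, jitterSdCm) else 0
    rad <- pose@heading * pi / 180
    nx <- pose@x + dist * cos(rad)
    ny <- pose@y + dist * sin(rad)
    b <- arena@bounds
    if (nx < b["xmin"] || nx > b["xmax"] || ny < b["ymin"] || ny > b["ymax"]) {
      return(pose)  # hit the wall: moved back to the previous pose
    }
    return(robotPose(nx, ny, pose@heading))
  }
  turn <- switch(command, TURN_LEFT = 30, TURN_RIGHT = -30,
                 stop("unknown command: ", command, call. = FALSE))
  if (jitterSdDeg > 0) turn <- turn + rnorm(1, 0, jitterSdDeg)
  robotPose(pose@x, pose@y, pose@heading + turn)
}

#' Track progress through the target sequence
#'
#' Targets must be visited in label order 1 -> 2 -> 3 -> 4, wrapping
#' back to 1 after target four. A pose whose position lies inside (or
#' exactly on the boundary of) the next expected target's rectangle
#' scores it with the cumulative time and movement count.
#'
#' @param pose Current [RobotPose-class].
#' @param arena An [Arena-class].
#' @param progress List with `nextTarget` (label expected next) and
#'   `reached` (data.frame of `target`, `cumSeconds`, `cumMovements`);
#'   start with `newProgress()`.
#' @param cumSeconds,cumMovements Elapsed control time (s) and command
#'   count at this volume.
#' @return Updated progress list.
#' @export
checkTargets <- function(pose, arena, progress, cumSeconds = 0, cumMovements = 0L) {
  t <- arena@targets
  row <- t[t$label == progress$nextTarget, ]
  inside <- pose@x >= row$cx - row$w / 2 & pose@x <= row$cx + row$w / 2 &
    pose@y >= row$cy - row$h / 2 & pose@y <= row$cy + row$h / 2
  if (inside) {
    progress$reached <- rbind(progress$reached, data.frame(
      target = nrow(progress$reached) + 1L,
      label = row$label,
      cumSeconds = cumSeconds,
      cumMovements = as.integer(cumMovements)
    ))
    progress$nextTarget <- if (row$label == max(t$label)) min(t$label) else row$label + 1L
  }
  progress
}

#' @rdname checkTargets
#' @param startTarget Label of the first target to reach (default 1).
#' @export
newProgress <- function(startTarget = 1L) {
  list(nextTarget = as.integer(startTarget),
       reached = data.frame(target = integer(), label = integer(),
                            cumSeconds = numeric(), cumMovements = integer()))
}

# Greedy planner user model: attends toward the action that brings the
# robot closer to the next expected target, CENTER during refractory.
# Headings and bearings in degrees; positive angle difference -> LEFT.
plannerAction <- function(pose, target) {
  bearing <- atan2(target$cy - pose@y, target$cx - pose@x) * 180 / pi
  d <- angleDiff(bearing, pose@heading)
  if (abs(d) <= 15) "UP" else if (d > 0) "LEFT" else "RIGHT"
}
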