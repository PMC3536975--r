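test_that("an all-CENTER stream never commands", {
  st <- controlState()
  for (t in 1:60) {
    out <- controlStep(st, "CENTER")
    st <- out$state
    expect_true(is.na(out$command))
  }
  expect_equal(st@commandsIssued, 0L)
})

test_that("a saturated stream matches the state-machine enumeration oracle", {
  # oracle: explicit simulation of the refractory counter
  n <- 725L
  oracleCmd <- logical(n)
  refr <- 0L
  for (t in seq_len(n)) {
    if (refr > 0L) refr <- refr - 1L else { oracleCmd[t] <- TRUE; refr <- 5L }
  }
  st <- controlState()
  got <- logical(n)
  for (t in seq_len(n)) {
    out <- controlStep(st, "UP")
    st <- out$state
    got[t] <- !is.na(out$command)
    if (got[t]) expect_equal(out$command, "FORWARD")
  }
  expect_equal(got, oracleCmd)
  expect_equal(min(diff(which(got))), 6L)  # 1 movement + 4 washout + next
})

test_that("video is off exactly during the four washout volumes", {
  st <- controlState()
  videoTrace <- logical(8)
  for (t in 1:8) {
    out <- controlStep(st, if (t == 1) "RIGHT" else "CENTER")
    st <- out$state
    videoTrace[t] <- st@videoOn
  }
  # command volume: video on; movement volume: on; washout 4: off; idle: on
  expect_equal(videoTrace, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("opposite turns cancel and forward moves follow the heading", {
  arena <- defaultArena()
  p0 <- robotPose(200, 250, 137)
  p1 <- executeCommand(p0, "TURN_RIGHT", arena)
  p2 <- executeCommand(p1, "TURN_LEFT", arena)
  expect_equal(c(p2@x, p2@y, p2@heading), c(p0@x, p0@y, p0@heading))
  f <- executeCommand(executeCommand(robotPose(100, 100, 90), "FORWARD", arena),
                      "FORWARD", arena)
  expect_equal(c(f@x, f@y), c(100, 200))
})

test_that("a forward move into a wall leaves the pose unchanged", {
  arena <- defaultArena()
  nearWall <- robotPose(390, 250, 0)  # 10 cm from the east wall
  after <- executeCommand(nearWall, "FORWARD", arena)
  expect_equal(c(after@x, after@y, after@heading), c(390, 250, 0))
})

test_that("targets only count in sequence, on closed rectangles, and wrap", {
  arena <- defaultArena()
  prog <- newProgress(1L)
  # standing inside target 2 while expecting target 1: no credit
  prog2 <- checkTargets(robotPose(300, 400, 0), arena, prog, 10, 1L)
  expect_equal(nrow(prog2$reached), 0L)
  # a boundary pose counts (target 1 spans x 87.5..112.5, y 375..425)
  prog3 <- checkTargets(robotPose(87.5, 375, 0), arena, prog, 20, 2L)
  expect_equal(prog3$reached$label, 1L)
  expect_equal(prog3$nextTarget, 2L)
  # reaching target 4 wraps the expectation back to 1
  prog4 <- list(nextTarget = 4L, reached = prog$reached)
  prog5 <- checkTargets(robotPose(100, 100, 0), arena, prog4, 30, 3L)
  expect_equal(prog5$nextTarget, 1L)
})

test_that("the oracle-decoded planner run reaches all four targets", {
  res <- runClosedLoop(decoder = "oracle", seed = 1)
  reached <- targetsReached(res$log)
  expect_gte(nrow(reached), 4L)
  expect_equal(reached$label[1:4], 1:4)
  expect_true(all(diff(reached$cumSeconds) > 0))
  expect_true(all(diff(reached$cumMovements) > 0))
})

test_that("command pacing respects the 10-TR minimum with the rise model", {
  res <- runClosedLoop(decoder = "oracle", seed = 2)
  rec <- sessionRecords(res$log)
  cmdVols <- which(!is.na(rec$command))
  expect_lte(length(cmdVols), 725 %/% 10)
  expect_gte(min(diff(cmdVols)), 10L)
})

test_that("the pose never leaves the arena", {
  res <- runClosedLoop(decoder = "oracle", seed = 3)
  rec <- sessionRecords(res$log)
  b <- defaultArena()@bounds
  expect_true(all(rec$x >= b["xmin"] & rec$x <= b["xmax"]))
  expect_true(all(rec$y >= b["ymin"] & rec$y <= b["ymax"]))
})

test_that("closed-loop runs are deterministic given the seed", {
  r1 <- runClosedLoop(decoder = "oracle", seed = 5)
  r2 <- runClosedLoop(decoder = "oracle", seed = 5)
  expect_identical(sessionRecords(r1$log), sessionRecords(r2$log))
  expect_identical(targetsReached(r1$log), targetsReached(r2$log))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSessionLog(r1$log, d1)
  writeSessionLog(r2$log, d2)
  expect_identical(readLines(file.path(d1, "control_log.tsv")),
                   readLines(file.path(d2, "control_log.tsv")))
})

test_that("the summary table mirrors the cumulative-time format", {
  res <- runClosedLoop(decoder = "oracle", seed = 1)
  s <- sessionSummary(res$log)
  expect_true(all(grepl("^\\d+ \\(\\d+\\)$", s$formatted)))
  # cumulative times are whole volumes times the TR
  vols <- s$cumSeconds / 1.62
  expect_equal(vols, round(vols), tolerance = 1e-9)
})

test_that("the decoded closed loop issues commands and moves the robot", {
  p <- scanProtocol(matrixSize = c(24L, 24L, 12L), nControl = 120L)
  res <- runClosedLoop(protocol = p, decoder = "svm", seed = 5)
  rec <- sessionRecords(res$log)
  expect_gt(sum(!is.na(rec$command)), 0L)
  expect_lte(sum(!is.na(rec$command)), 120 %/% 6)
  expect_true(length(res$mask) > 0)
})
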