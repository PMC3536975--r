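test_that("default cue schedule has 54 alternating balanced trials", {
  sched <- buildCueSchedule(scanProtocol(), seed = 1)
  tr <- trials(sched)
  expect_equal(nrow(tr), 54L)
  expect_equal(unname(table(tr$direction)["CENTER"]), 27L, ignore_attr = TRUE)
  counts <- table(tr$direction[tr$direction != "CENTER"])
  expect_equal(sort(unname(counts)), c(9L, 9L, 9L), ignore_attr = TRUE)
  expect_equal(sum(tr$length), 270L)
})

test_that("schedule is deterministic and directional trials never touch", {
  expect_identical(buildCueSchedule(scanProtocol(), 7),
                   buildCueSchedule(scanProtocol(), 7))
  for (seed in 1:5) {
    tr <- trials(buildCueSchedule(scanProtocol(), seed))
    dir <- tr$direction != "CENTER"
    expect_false(any(dir[-1] & dir[-length(dir)]))
    counts <- table(factor(tr$direction[dir], levels = c("RIGHT", "LEFT", "UP")))
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("smallest schedule is one CENTER and one directional trial", {
  p <- scanProtocol(nLocalizer = 10L, nControl = 0L, matrixSize = c(4, 4, 2))
  tr <- trials(buildCueSchedule(p, 1))
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$direction[1], "CENTER")
  expect_true(tr$direction[2] %in% c("RIGHT", "LEFT", "UP"))
})

test_that("a non-tileable localizer phase is rejected", {
  expect_error(scanProtocol(nLocalizer = 13L), "divisible")
})

test_that("regressors with an impulse kernel reproduce the boxcar", {
  p <- scanProtocol(nLocalizer = 30L, nControl = 0L, matrixSize = c(4, 4, 2))
  sched <- buildCueSchedule(p, 2)
  r <- attentionRegressors(sched, delayHrf(0L))
  states <- scheduleStates(sched)
  for (d in c("RIGHT", "LEFT", "UP", "CENTER")) {
    expect_equal(r$regressors[, d], as.numeric(states == d))
  }
})

test_that("directional regressors are causal", {
  sched <- buildCueSchedule(scanProtocol(), seed = 3)
  r <- attentionRegressors(sched, canonicalHrf(1.62))
  tr <- trials(sched)
  for (d in c("RIGHT", "LEFT", "UP")) {
    first <- min(tr$start[tr$direction == d])
    if (first > 1) expect_equal(r$regressors[seq_len(first - 1), d], rep(0, first - 1))
  }
})

test_that("regressor values match the direct discrete convolution oracle", {
  # boxcar of length 5 starting at 0-based volume 10, kernel length 12
  kernel <- seq(0.5, 0.05, length.out = 12)
  hrf <- new("Hrf", kernel = kernel, lagVolumes = 0L)
  states <- rep("CENTER", 40)
  states[11:15] <- "RIGHT"   # 0-based volumes 10..14
  r <- attentionRegressors(NULL, hrf, states = states)
  # 0-based volume 14 = 1-based 15: overlap with kernel[1..5]
  expect_equal(unname(r$regressors[15, "RIGHT"]), sum(kernel[1:5]))
  # full oracle over the series
  oracle <- vapply(seq_along(states), function(t) {
    j <- seq_len(min(t, 12))
    sum(kernel[j] * (states[t - j + 1] == "RIGHT"))
  }, 0)
  expect_equal(unname(r$regressors[, "RIGHT"]), oracle, tolerance = 1e-10)
})

test_that("noiseless zero-amplitude session reproduces the phantom exactly", {
  p <- scanProtocol(nLocalizer = 20L, nControl = 0L, matrixSize = c(10, 10, 6))
  ph <- defaultPhantom(c(10, 10, 6), amplitude = 0)
  ses <- synthesizeSession(p, buildCueSchedule(p, 1), ph, canonicalHrf(1.62),
                           noiselessModel())
  for (t in seq_len(20)) {
    expect_identical(ses@volumes[, , , t], ph@baseline)
  }
})

test_that("sessions are bit-identical under the same seed", {
  p <- scanProtocol(nLocalizer = 10L, nControl = 5L, matrixSize = c(8, 8, 4))
  args <- list(p, buildCueSchedule(p, 1), defaultPhantom(c(8, 8, 4)),
               canonicalHrf(1.62), noiseModel(seed = 11),
               controlScript = rep("UP", 5))
  expect_identical(do.call(synthesizeSession, args)@volumes,
                   do.call(synthesizeSession, args)@volumes)
})

test_that("sustained attention reaches the steady-state plateau", {
  dims <- c(6L, 6L, 4L)
  baseline <- array(1000, dims)
  mask <- array(TRUE, dims)
  roiVox <- 33L
  ph <- new("Phantom", baseline = baseline, brainMask = mask,
            rois = list(RIGHT = list(indices = roiVox, amplitude = 0.02)))
  hrf <- canonicalHrf(1.62)
  p <- scanProtocol(nLocalizer = 10L, nControl = 30L, matrixSize = dims)
  ses <- synthesizeSession(p, buildCueSchedule(p, 1), ph, hrf, noiselessModel(),
                           controlScript = rep("RIGHT", 30))
  plateau <- 1000 * (1 + 0.02 * sum(hrfKernel(hrf)))
  expect_equal(ses@volumes[, , , 40][roiVox], plateau, tolerance = 1e-9)
})

test_that("non-ROI voxels are constant when noise and motion are off", {
  p <- scanProtocol(nLocalizer = 20L, nControl = 0L, matrixSize = c(10, 10, 6))
  ph <- defaultPhantom(c(10, 10, 6))
  ses <- synthesizeSession(p, buildCueSchedule(p, 2), ph, canonicalHrf(1.62),
                           noiselessModel())
  nonRoi <- setdiff(seq_len(prod(dim(ph@baseline))), unlist(roiIndices(ph)))
  flat <- matrix(ses@volumes, ncol = 20)[nonRoi, ]
  expect_equal(max(apply(flat, 1, function(x) diff(range(x)))), 0)
})

test_that("ground-truth states match the schedule over the localizer", {
  p <- scanProtocol(nLocalizer = 30L, nControl = 4L, matrixSize = c(6, 6, 4))
  sched <- buildCueSchedule(p, 5)
  ses <- synthesizeSession(p, sched, defaultPhantom(c(6, 6, 4)), canonicalHrf(1.62),
                           noiselessModel(), controlScript = rep("CENTER", 4))
  expect_identical(trueStates(ses)[1:30], scheduleStates(sched))
})

test_that("a mismatched control script is rejected", {
  p <- scanProtocol(nLocalizer = 10L, nControl = 5L, matrixSize = c(6, 6, 4))
  expect_error(
    synthesizeSession(p, buildCueSchedule(p, 1), defaultPhantom(c(6, 6, 4)),
                      canonicalHrf(1.62), noiselessModel(),
                      controlScript = rep("CENTER", 3)),
    "control"
  )
})
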