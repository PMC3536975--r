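fourClouds <- function(n = 30, sep = 6, seed = 1) {
  set.seed(seed)
  ctrs <- list(RIGHT = c(0, 0), LEFT = c(sep, sep), UP = c(0, sep),
               CENTER = c(sep, 0))
  x <- do.call(rbind, lapply(ctrs, function(c) {
    cbind(rnorm(n, c[1]), rnorm(n, c[2]))
  }))
  y <- factor(rep(names(ctrs), each = n),
              levels = c("RIGHT", "LEFT", "UP", "CENTER"))
  ord <- sample(nrow(x))
  list(x = x[ord, ], y = y[ord])
}

test_that("lag-0 labels equal the per-volume schedule states", {
  p <- scanProtocol(nLocalizer = 30L, nControl = 0L, matrixSize = c(4, 4, 2))
  sched <- buildCueSchedule(p, 1)
  feats <- matrix(rnorm(30 * 4), 30, 4)
  ts <- buildTrainingSet(sched, feats, svmConfig(labelLag = 0L))
  expect_equal(as.character(ts$y), scheduleStates(sched))
  expect_equal(nrow(ts$x), 30L)
})

test_that("lagged labels follow the index-shift oracle", {
  # trial RIGHT at 0-based volumes 5-9 -> lag 2 labels volumes 7-11
  states <- rep("CENTER", 20)
  states[6:10] <- "RIGHT"
  trials <- data.frame(direction = c("CENTER", "RIGHT", "CENTER", "CENTER"),
                       start = c(1L, 6L, 11L, 16L), length = 5L)
  sched <- new("CueSchedule", trials = trials, nVolumes = 20L)
  feats <- matrix(0, 20, 2)
  ts <- buildTrainingSet(sched, feats, svmConfig(labelLag = 2L))
  expect_equal(ts$volumes[ts$y == "RIGHT"], 8:12)
})

test_that("the labeled set drops exactly the first lag volumes", {
  sched <- buildCueSchedule(scanProtocol(), 2)
  feats <- matrix(0, 270, 2)
  for (lag in c(0L, 2L, 4L)) {
    ts <- buildTrainingSet(sched, feats, svmConfig(labelLag = lag))
    expect_equal(nrow(ts$x), 270L - lag)
  }
})

test_that("linearly separable clouds are learned perfectly with C = 1", {
  d <- fourClouds()
  expect_equal(svmConfig()@cParam, 1)
  model <- trainClassifier(d)
  pred <- apply(d$x, 1, classifyVolume, model = model)
  expect_equal(mean(pred == as.character(d$y)), 1)
  expect_length(model@pairs, 6L)
})

test_that("duplicating every training example leaves decisions unchanged", {
  d <- fourClouds(n = 20, seed = 2)
  m1 <- trainClassifier(d)
  m2 <- trainClassifier(list(x = rbind(d$x, d$x), y = c(d$y, d$y)))
  set.seed(3)
  probes <- cbind(rnorm(200, 3, 4), rnorm(200, 3, 4))
  p1 <- apply(probes, 1, classifyVolume, model = m1)
  p2 <- apply(probes, 1, classifyVolume, model = m2)
  expect_gt(mean(p1 == p2), 0.98)
})

test_that("a missing class is rejected", {
  d <- fourClouds(n = 10)
  keep <- d$y != "UP"
  expect_error(trainClassifier(list(x = d$x[keep, ], y = d$y[keep])), "UP")
})

craftedClassifier <- function(pairDecisions) {
  # build an AttnClassifier whose six decision values are fixed signs
  combos <- utils::combn(c("RIGHT", "LEFT", "UP", "CENTER"), 2)
  pairs <- lapply(seq_len(ncol(combos)), function(j) {
    list(classA = combos[1, j], classB = combos[2, j],
         weights = 0, bias = pairDecisions[j])
  })
  new("AttnClassifier", pairs = pairs, classes = c("RIGHT", "LEFT", "UP", "CENTER"),
      featureDim = 1L)
}

voteOracle <- function(pairDecisions) {
  combos <- utils::combn(c("RIGHT", "LEFT", "UP", "CENTER"), 2)
  votes <- setNames(integer(4), c("RIGHT", "LEFT", "UP", "CENTER"))
  for (j in seq_len(ncol(combos))) {
    w <- if (pairDecisions[j] > 0) combos[1, j] else combos[2, j]
    votes[w] <- votes[w] + 1L
  }
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1) winners else "CENTER"
}

test_that("a three-way cycle among the directions falls back to CENTER", {
  # pairs: R/L, R/U, R/C, L/U, L/C, U/C
  # R beats L, U beats R, L beats U, each direction beats CENTER
  dec <- c(1, -1, 1, 1, 1, 1)
  m <- craftedClassifier(dec)
  expect_equal(classifyVolume(m, 0), "CENTER")
  expect_equal(voteOracle(dec), "CENTER")
})

test_that("a unanimous winner takes the volume", {
  dec <- c(1, 1, 1, -1, 1, -1)  # RIGHT wins its three pairings
  expect_equal(classifyVolume(craftedClassifier(dec), 0), "RIGHT")
})

test_that("voting matches the exhaustive tally oracle for all sign patterns", {
  signs <- expand.grid(rep(list(c(-1, 1)), 6))
  for (i in seq_len(nrow(signs))) {
    dec <- as.numeric(signs[i, ])
    expect_equal(classifyVolume(craftedClassifier(dec), 0), voteOracle(dec))
  }
})

test_that("classification is invariant to the storage order of the pairs", {
  d <- fourClouds(n = 15, seed = 4)
  m <- trainClassifier(d)
  set.seed(5)
  shuffled <- m
  shuffled@pairs <- m@pairs[sample(6)]
  probes <- cbind(rnorm(100, 3, 4), rnorm(100, 3, 4))
  expect_equal(apply(probes, 1, classifyVolume, model = m),
               apply(probes, 1, classifyVolume, model = shuffled))
})

test_that("a dimension mismatch is rejected", {
  m <- trainClassifier(fourClouds(n = 10))
  expect_error(classifyVolume(m, c(1, 2, 3)), "length 3")
})

test_that("the decoder serializes and restores losslessly", {
  d <- fourClouds(n = 12, seed = 6)
  m <- trainClassifier(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeClassifier(m, path)
  m2 <- readClassifier(path)
  probes <- cbind(rnorm(50, 3, 4), rnorm(50, 3, 4))
  expect_equal(apply(probes, 1, classifyVolume, model = m),
               apply(probes, 1, classifyVolume, model = m2))
})
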