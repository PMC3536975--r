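test_that("a linear series is removed completely", {
  y <- 3 + 0.5 * (1:80)
  expect_lt(max(abs(detrendBatch(y, 200))), 1e-9)
})

test_that("lambda = 0 removes everything", {
  set.seed(1)
  expect_lt(max(abs(detrendBatch(rnorm(40), 0))), 1e-12)
})

test_that("detrending matches the dense linear-solve oracle", {
  set.seed(2)
  y <- rnorm(60, mean = 1000, sd = 10)
  d2 <- diff(diag(60), differences = 2)
  oracle <- y - solve(diag(60) + 200^2 * crossprod(d2), y)
  expect_equal(detrendBatch(y, 200), oracle, tolerance = 1e-8)
})

test_that("detrending is linear in its input", {
  set.seed(3)
  x <- rnorm(50); y <- rnorm(50)
  lhs <- detrendBatch(2.5 * x - 1.3 * y, 200)
  rhs <- 2.5 * detrendBatch(x, 200) - 1.3 * detrendBatch(y, 200)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("larger lambda yields a smoother removed trend", {
  set.seed(4)
  y <- cumsum(rnorm(120)) + rnorm(120)
  energies <- vapply(c(10, 50, 200, 1000), function(l) {
    trend <- y - detrendBatch(y, l)
    sum(diff(trend, differences = 2)^2)
  }, 0)
  expect_true(all(diff(energies) < 0))
})

test_that("short series are rejected", {
  expect_error(detrendBatch(c(1, 2), 200), "3 samples")
})

test_that("the fitted normalizer standardizes its own training series", {
  set.seed(5)
  y <- matrix(rnorm(80 * 6, mean = 1000, sd = 12), 80, 6)
  y <- y + outer(seq_len(80), runif(6, -0.5, 0.5))   # per-voxel drift
  nm <- fitNormalizer(y)
  z <- normalizeSeries(nm)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(apply(z, 2, var), rep(1, 6), tolerance = 1e-9)
})

test_that("doubling raw intensities doubles baseline and scale", {
  set.seed(6)
  y <- matrix(rnorm(60 * 3, 500, 8), 60, 3)
  n1 <- fitNormalizer(y)
  n2 <- fitNormalizer(2 * y)
  expect_equal(n2@baseline, 2 * n1@baseline, tolerance = 1e-10)
  expect_equal(n2@scale, 2 * n1@scale, tolerance = 1e-10)
})

test_that("detrending leaves the signal level unbiased for constant-plus-noise", {
  # the recovered level (raw mean minus detrended mean) estimates the
  # constant to within Monte-Carlo error
  const <- 850
  errs <- vapply(1:30, function(s) {
    set.seed(400 + s)
    y <- const + rnorm(100, 0, 10)
    mean(y) - mean(detrendBatch(y, 200)) - const
  }, 0)
  se <- 10 / sqrt(100)
  expect_lt(abs(mean(errs)), 3 * se / sqrt(30))
})

test_that("streaming control features stay in a standardized range", {
  set.seed(7)
  nVox <- 5L
  loc <- matrix(rnorm(120 * nVox, 1000, 10), 120, nVox)
  nm <- fitNormalizer(loc, detrendConfig(), nTotal = 220L)
  feats <- matrix(0, 100, nVox)
  for (t in 1:100) {
    out <- processControlVolume(nm, rnorm(nVox, 1000, 10))
    nm <- out$normalizer
    feats[t, ] <- out$features
  }
  expect_lt(stats::quantile(abs(feats), 0.95), 3)
})

test_that("streaming detrending attenuates control-phase drift", {
  set.seed(8)
  nVox <- 4L
  loc <- matrix(rnorm(120 * nVox, 1000, 10), 120, nVox)
  nm <- fitNormalizer(loc, detrendConfig(), nTotal = 320L)
  drift <- seq(0, 60, length.out = 200)  # strong added ramp
  rawFeat <- detFeat <- matrix(0, 200, nVox)
  for (t in 1:200) {
    raw <- rnorm(nVox, 1000, 10) + drift[t]
    out <- processControlVolume(nm, raw)
    nm <- out$normalizer
    detFeat[t, ] <- out$features
    rawFeat[t, ] <- (raw - nm@baseline - 1000) / nm@scale
  }
  slope <- function(z) abs(coef(lm(z ~ seq_along(z)))[2])
  sDet <- mean(apply(detFeat, 2, slope))
  sRaw <- mean(apply(rawFeat, 2, slope))
  expect_lt(sDet * 5, sRaw)
})

test_that("a saturating window reproduces full-history batch detrending", {
  set.seed(9)
  nVox <- 3L
  loc <- matrix(rnorm(50 * nVox, 1000, 10), 50, nVox)
  nm <- fitNormalizer(loc, detrendConfig(controlWindow = 500L), nTotal = 80L)
  newRows <- matrix(rnorm(20 * nVox, 1000, 10), 20, nVox)
  for (t in 1:20) {
    out <- processControlVolume(nm, newRows[t, ])
    nm <- out$normalizer
  }
  full <- detrendBatch(rbind(loc, newRows), 200)
  expected <- (full[70, ] - nm@baseline) / nm@scale
  expect_equal(out$features, expected, tolerance = 1e-10)
})

test_that("control processing before fitting is rejected", {
  nm <- new("VoxelNormalizer", baseline = 0, scale = 1,
            rawHistory = matrix(NA_real_, 10, 1), nSeen = 0L,
            config = detrendConfig())
  expect_error(processControlVolume(nm, 1), "fitted")
})
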