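vmm <- c(1.848, 1.848, 2)

test_that("identity resampling reproduces the volume at grid points", {
  set.seed(1)
  vol <- smoothBlob() + array(runif(20 * 20 * 16), c(20, 20, 16)) * 50
  out <- resampleVolume(vol, identityTransform(), voxelMm = vmm)
  expect_lt(max(abs(out - vol)) / max(abs(vol)), 1e-6)
})

test_that("an exact one-voxel translation shifts the grid", {
  set.seed(2)
  dims <- c(16L, 16L, 10L)
  vol <- array(runif(prod(dims), 0, 1000), dims)
  tf <- rigidTransform(translation = c(vmm[1], 0, 0),
                       center = c(0, 0, 0))
  out <- resampleVolume(vol, tf, voxelMm = vmm)
  expect_lt(max(abs(out[1:15, , ] - vol[2:16, , ])), 1e-6)
})

test_that("transform round trips recover interior voxels", {
  vol <- smoothBlob()
  ctr <- (dim(vol) - 1) / 2 * vmm
  tf <- rigidTransform(rotation = c(0.05, -0.03, 0.08),
                       translation = c(1.5, -0.8, 0.5), center = ctr)
  back <- resampleVolume(resampleVolume(vol, tf, voxelMm = vmm),
                         invertTransform(tf), voxelMm = vmm)
  inner <- max(abs(back[6:15, 6:15, 5:12] - vol[6:15, 6:15, 5:12]))
  expect_lt(inner / max(abs(vol)), 1e-3)
})

test_that("composing a transform with its inverse is the identity", {
  tf <- rigidTransform(rotation = c(0.1, -0.2, 0.15),
                       translation = c(3, -2, 1), center = c(10, 12, 8))
  inv <- invertTransform(tf)
  pts <- matrix(runif(30, 0, 40), ncol = 3)
  expect_equal(covisaBCI:::applyTransform(inv, covisaBCI:::applyTransform(tf, pts)),
               pts, tolerance = 1e-10)
  idPar <- transformParameters(identityTransform())
  expect_true(all(idPar == 0))
})

test_that("self-registration returns near-identity parameters", {
  vol <- toyPhantom()@baseline
  tf <- registerVolume(vol, vol, voxelMm = vmm, seed = 1)
  expect_lt(max(abs(transformParameters(tf))), 0.05)
})

test_that("a known injected translation is recovered within 0.2 voxel", {
  template <- toyPhantom()@baseline
  ctr <- (dim(template) - 1) / 2 * vmm
  dVox <- c(1.5, -0.8, 0.5)
  inj <- rigidTransform(translation = dVox * vmm, center = ctr)
  moving <- resampleVolume(template, inj, voxelMm = vmm)
  est <- registerVolume(moving, template, voxelMm = vmm, seed = 4)
  # the estimate maps template to moving coordinates: the inverse shift
  errVox <- abs(transformParameters(est)[4:6] + dVox * vmm) / vmm
  expect_lt(max(errVox), 0.2)
})

test_that("registration defaults follow the online protocol", {
  cfg <- registrationConfig()
  expect_equal(cfg@iterations, 50L)
  expect_equal(cfg@sigmaVoxels, 1)
})

test_that("a constant template is rejected as degenerate", {
  flat <- array(7, c(8, 8, 4))
  expect_error(registerVolume(flat + rnorm(256), flat, voxelMm = vmm),
               "degenerate")
})

test_that("registration lowers the smoothed SSD of motion-corrupted volumes", {
  template <- toyPhantom()@baseline
  ctr <- (dim(template) - 1) / 2 * vmm
  drops <- vapply(1:3, function(s) {
    set.seed(100 + s)
    inj <- rigidTransform(rotation = runif(3, -0.02, 0.02),
                          translation = runif(3, -2, 2), center = ctr)
    moving <- resampleVolume(template, inj, voxelMm = vmm)
    est <- registerVolume(moving, template, voxelMm = vmm, seed = s)
    ssd0 <- covisaBCI:::smoothedSsd(moving, template,
                                    identityTransform(ctr), vmm)
    ssd1 <- covisaBCI:::smoothedSsd(moving, template, est, vmm)
    ssd1 / ssd0
  }, 0)
  expect_lt(mean(drops), 0.2)
})

test_that("register + resample reduces frame-to-template error on a moving session", {
  dims <- c(24L, 24L, 12L)
  nVol <- 6L
  p <- scanProtocol(nLocalizer = 5L, nControl = 1L, matrixSize = dims)
  mt <- matrix(0, nVol, 6)
  set.seed(9)
  mt[-1, 1:3] <- runif((nVol - 1) * 3, -0.015, 0.015)
  mt[-1, 4:6] <- runif((nVol - 1) * 3, -1.5, 1.5)
  ses <- synthesizeSession(p, buildCueSchedule(p, 1), toyPhantom(),
                           canonicalHrf(1.62),
                           noiseModel(whiteSd = 0, driftRwSd = 0,
                                      driftLinearSd = 0, motionTrace = mt,
                                      seed = 1),
                           controlScript = "CENTER")
  template <- ses@volumes[, , , 1]
  inner <- as.matrix(expand.grid(5:20, 5:20, 3:10))
  for (t in 2:nVol) {
    vol <- ses@volumes[, , , t]
    est <- registerVolume(vol, template, voxelMm = vmm, seed = t)
    fixed <- resampleVolume(vol, est, voxelMm = vmm)
    madBefore <- mean(abs(vol[inner] - template[inner]))
    madAfter <- mean(abs(fixed[inner] - template[inner]))
    expect_lt(madAfter, madBefore)
  }
})
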