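# 3D interpolation and smoothing primitives used by the motion
# correction stage. Coordinates are 0-based voxel indices; world mm
# coordinates are index * voxelMm.

# separable Gaussian smoothing with edge replication; sigma in voxels
gaussianSmooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  radius <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  w <- w / sum(w)
  dims <- dim(vol)
  for (axis in 1:3) {
    n <- dims[axis]
    out <- array(0, dims)
    for (o in (-radius):radius) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)   # replicate edges
      shifted <- switch(axis,
                        vol[idx, , , drop = FALSE],
                        vol[, idx, , drop = FALSE],
                        vol[, , idx, drop = FALSE])
      out <- out + w[o + radius + 1L] * shifted
    }
    vol <- out
  }
  vol
}

# trilinear interpolation at 0-based voxel coordinates (n x 3 matrix);
# points outside the grid get `outValue`
interpolateLinear <- function(vol, pts, outValue = 0) {
  dims <- dim(vol)
  n <- nrow(pts)
  inside <- pts[, 1] >= 0 & pts[, 1] <= dims[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= dims[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= dims[3] - 1
  out <- rep(outValue, n)
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- pmin(floor(p), rbind(dims - 2)[rep(1, nrow(p)), ])
  f <- p - i0
  acc <- numeric(nrow(p))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    acc <- acc + wt * vol[idx]
  }
  out[inside] <- acc
  out
}

# --- interpolating cubic B-spline ------------------------------------
# Prefiltering (recursive causal/anticausal filter, pole sqrt(3)-2,
# mirror boundaries) turns samples into B-spline coefficients so that
# evaluation at grid points reproduces the input exactly.

bsplinePrefilter1d <- function(x) {
  # x: matrix, filtering along rows; vectorized over columns
  z <- sqrt(3) - 2
  n <- nrow(x)
  if (n == 1L) return(x)
  x <- x * 6
  cp <- matrix(0, n, ncol(x))
  # causal init under whole-sample mirror boundaries; exact closed form
  # for short signals, truncated geometric sum otherwise
  horizon <- ceiling(log(.Machine$double.eps) / log(abs(z)))
  if (horizon < n) {
    zk <- z^(seq_len(horizon) - 1)
    cp[1, ] <- as.numeric(zk %*% x[seq_len(horizon), , drop = FALSE])
  } else {
    k <- seq_len(n)
    w <- z^(k - 1) + z^(2 * n - k - 1)
    w[1] <- 1
    w[n] <- z^(n - 1)
    cp[1, ] <- as.numeric(w %*% x) / (1 - z^(2 * n - 2))
  }
  for (k in 2:n) cp[k, ] <- x[k, ] + z * cp[k - 1L, ]
  cm <- matrix(0, n, ncol(x))
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1L, ])
  for (k in (n - 1L):1L) cm[k, ] <- z * (cm[k + 1L, ] - cp[k, ])
  cm
}

bsplineCoefficients <- function(vol) {
  dims <- dim(vol)
  m <- matrix(vol, nrow = dims[1])
  m <- bsplinePrefilter1d(m)
  vol <- array(m, dims)
  vol <- aperm(vol, c(2, 1, 3))
  m <- bsplinePrefilter1d(matrix(vol, nrow = dims[2]))
  vol <- aperm(array(m, dims[c(2, 1, 3)]), c(2, 1, 3))
  vol <- aperm(vol, c(3, 1, 2))
  m <- bsplinePrefilter1d(matrix(vol, nrow = dims[3]))
  aperm(array(m, dims[c(3, 1, 2)]), c(2, 3, 1))
}

# mirror a 1-based index into [1, n]
mirrorIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i <- ifelse(i < 0L, i + period, i)
  as.integer(ifelse(i >= n, period - i, i) + 1L)
}

cubicWeights <- function(f) {
  cbind((1 - f)^3 / 6,
        2 / 3 - f^2 + f^3 / 2,
        2 / 3 - (1 - f)^2 + (1 - f)^3 / 2,
        f^3 / 6)
}

# cubic B-spline evaluation at 0-based voxel coordinates given
# prefiltered coefficients; outside the grid -> `outValue`
interpolateBspline <- function(coef, pts, outValue = 0) {
  dims <- dim(coef)
  n <- nrow(pts)
  inside <- pts[, 1] >= 0 & pts[, 1] <= dims[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= dims[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= dims[3] - 1
  out <- rep(outValue, n)
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  i0 <- floor(p)
  f <- p - i0
  wx <- cubicWeights(f[, 1]); wy <- cubicWeights(f[, 2]); wz <- cubicWeights(f[, 3])
  ix <- lapply(0:3, function(d) mirrorIndex(as.integer(i0[, 1]) + d, dims[1]))
  iy <- lapply(0:3, function(d) mirrorIndex(as.integer(i0[, 2]) + d, dims[2]))
  iz <- lapply(0:3, function(d) mirrorIndex(as.integer(i0[, 3]) + d, dims[3]))
  acc <- numeric(nrow(p))
  for (dz in 1:4) for (dy in 1:4) for (dx in 1:4) {
    wt <- wx[, dx] * wy[, dy] * wz[, dz]
    acc <- acc + wt * coef[cbind(ix[[dx]], iy[[dy]], iz[[dz]])]
  }
  out[inside] <- acc
  out
}
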