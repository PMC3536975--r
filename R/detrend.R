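#' Construct detrending settings
#'
#' @param lambda Regularization parameter of the smoothness prior
#'   (default 200).
#' @param controlWindow Trailing history length in volumes used when
#'   detrending streaming control-phase samples (default 100).
#' @return A [DetrendConfig-class].
#' @export
detrendConfig <- function(lambda = 200, controlWindow = 100L) {
  new("DetrendConfig", lambda = lambda, controlWindow = as.integer(controlWindow))
}

# Cached Cholesky factor of (I + lambda^2 D2' D2) per (T, lambda); the
# control loop re-solves the same window length on every volume.
detrendCache <- new.env(parent = emptyenv())

detrendFactor <- function(n, lambda) {
  key <- sprintf("%d_%.12g", n, lambda)
  got <- detrendCache[[key]]
  if (!is.null(got)) return(got)
  d2 <- diff(diag(n), differences = 2)
  a <- diag(n) + lambda^2 * crossprod(d2)
  ch <- chol(a)
  if (length(ls(detrendCache)) > 32) rm(list = ls(detrendCache), envir = detrendCache)
  detrendCache[[key]] <- ch
  ch
}

#' Smoothness-priors detrending
#'
#' Estimates the low-frequency trend as the solution of
#' `(I + lambda^2 D2' D2) trend = series`, where D2 is the
#' (T-2) x T second-difference operator, and returns
#' `series - trend`. A series that is exactly linear is removed
#' completely (its second differences vanish), and `lambda = 0` returns
#' all zeros.
#'
#' @param series Numeric vector of length T, or a T x V matrix
#'   (columns detrended independently).
#' @param lambda Regularization parameter (default 200).
#' @return Detrended series of the same shape.
#' @examples
#' detrendBatch(3 + 0.5 * (1:50))  # ~0 everywhere
#' @export
detrendBatch <- function(series, lambda = 200) {
  vec <- is.null(dim(series))
  y <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  n <- nrow(y)
  if (n < 3L) stop("detrending needs at least 3 samples", call. = FALSE)
  assertScalarNumeric(lambda, "lambda", lower = 0)
  ch <- detrendFactor(n, lambda)
  trend <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  out <- y - trend
  if (vec) as.numeric(out) else out
}

#' Fit the per-voxel normalizer from the localizer series
#'
#' Detrends the complete localizer series of every masked voxel in
#' batch, then freezes each voxel's baseline (mean) and scale (standard
#' deviation) of the detrended series. The original raw values are kept
#' so later control volumes can be detrended over a trailing window of
#' the same history. Voxels whose detrended series has zero variance
#' cannot be normalized and are reported via the `zeroVariance`
#' attribute; exclude them from the mask upstream.
#'
#' @param localizerSeries T x V matrix of raw (motion-corrected)
#'   intensities of the masked voxels.
#' @param config A [DetrendConfig-class].
#' @param nTotal Total session length used to preallocate the raw
#'   history (default: localizer length + 1024).
#' @return A [VoxelNormalizer-class]; `attr(, "zeroVariance")` holds
#'   the offending column indices (empty when none).
#' @export
fitNormalizer <- function(localizerSeries, config = detrendConfig(),
                          nTotal = nrow(localizerSeries) + 1024L) {
  y <- as.matrix(localizerSeries)
  det <- detrendBatch(y, config@lambda)
  baseline <- colMeans(det)
  scale <- apply(det, 2, sd)
  bad <- which(scale <= 0)
  if (length(bad)) {
    warning(sprintf("%d voxel(s) have zero variance after detrending", length(bad)))
    scale[bad] <- 1  # keeps the object valid; caller must drop these voxels
  }
  hist <- matrix(NA_real_, nrow = max(nTotal, nrow(y)), ncol = ncol(y))
  hist[seq_len(nrow(y)), ] <- y
  out <- new("VoxelNormalizer", baseline = baseline, scale = scale,
             rawHistory = hist, nSeen = nrow(y), config = config)
  attr(out, "zeroVariance") <- bad
  out
}

#' Normalize the training series with a fitted normalizer
#'
#' @param normalizer A [VoxelNormalizer-class].
#' @param series T x V raw matrix (defaults to the stored localizer
#'   history).
#' @return T x V matrix of detrended, z-scored values.
#' @export
normalizeSeries <- function(normalizer, series = NULL) {
  stopifnot(is(normalizer, "VoxelNormalizer"))
  if (is.null(series)) {
    series <- normalizer@rawHistory[seq_len(normalizer@nSeen), , drop = FALSE]
  }
  det <- detrendBatch(series, normalizer@config@lambda)
  sweep(sweep(det, 2, normalizer@baseline), 2, normalizer@scale, "/")
}

#' Detrend and normalize one streaming control volume
#'
#' Appends the new raw values to the kept history, re-detrends the
#' trailing `controlWindow` of history, takes the newest detrended
#' sample and z-scores it with the frozen baseline and scale.
#'
#' @param normalizer A fitted [VoxelNormalizer-class].
#' @param newValues Raw intensities of the masked voxels for the new
#'   volume.
#' @return List with `features` (normalized vector) and `normalizer`
#'   (updated history).
#' @export
processControlVolume <- function(normalizer, newValues) {
  stopifnot(is(normalizer, "VoxelNormalizer"))
  if (normalizer@nSeen < 3L) {
    stop("normalizer must be fitted on the localizer before control use",
         call. = FALSE)
  }
  v <- as.numeric(newValues)
  if (length(v) != ncol(normalizer@rawHistory)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  n <- normalizer@nSeen + 1L
  if (n > nrow(normalizer@rawHistory)) {
    grown <- matrix(NA_real_, nrow(normalizer@rawHistory) + 1024L, length(v))
    grown[seq_len(normalizer@nSeen), ] <-
      normalizer@rawHistory[seq_len(normalizer@nSeen), , drop = FALSE]
    normalizer@rawHistory <- grown
  }
  normalizer@rawHistory[n, ] <- v
  normalizer@nSeen <- n
  w <- min(normalizer@config@controlWindow, n)
  windowed <- normalizer@rawHistory[(n - w + 1L):n, , drop = FALSE]
  det <- detrendBatch(windowed, normalizer@config@lambda)
  features <- (det[w, ] - normalizer@baseline) / normalizer@scale
  list(features = features, normalizer = normalizer)
}

setMethod("show", "VoxelNormalizer", function(object) {
  cat(sprintf("VoxelNormalizer: %d voxels, %d volumes of history, lambda = %g, window = %d\n",
              length(object@scale), object@nSeen, object@config@lambda,
              object@config@controlWindow))
})
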