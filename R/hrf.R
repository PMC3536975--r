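#' Canonical double-gamma haemodynamic response function
#'
#' Samples the standard double-gamma impulse response (peak near 5 s,
#' undershoot near 15 s) at TR resolution and normalizes the kernel to
#' unit sum, so that a sustained boxcar converges to a plateau response
#' of exactly 1 and ROI amplitudes read as fractional signal change at
#' plateau.
#'
#' @param tr Sampling interval in seconds.
#' @param durationSec Kernel support in seconds (default 30).
#' @param peakDelay,undershootDelay Gamma shape parameters (seconds).
#' @param undershootRatio Relative amplitude of the undershoot.
#' @return An [Hrf-class] object; `lagVolumes` is the peak sample index
#'   (0-based).
#' @examples
#' h <- canonicalHrf(1.62)
#' sum(hrfKernel(h))  # 1
#' @export
canonicalHrf <- function(tr = 1.62, durationSec = 30,
                         peakDelay = 6, undershootDelay = 16,
                         undershootRatio = 1 / 6) {
  t <- seq(0, durationSec, by = tr)
  k <- stats::dgamma(t, shape = peakDelay, rate = 1) -
    undershootRatio * stats::dgamma(t, shape = undershootDelay, rate = 1)
  k <- k / sum(k)
  new("Hrf", kernel = k, lagVolumes = as.integer(which.max(k) - 1L))
}

#' Pure-delay impulse response
#'
#' A degenerate alternative kernel that simply delays the boxcar by
#' `lagVolumes` samples, useful for sensitivity checks against the
#' double-gamma default.
#'
#' @param lagVolumes Delay in volumes.
#' @return An [Hrf-class] object.
#' @export
delayHrf <- function(lagVolumes = 0L) {
  lag <- as.integer(lagVolumes)
  new("Hrf", kernel = c(rep(0, lag), 1), lagVolumes = lag)
}

#' @rdname canonicalHrf
#' @param x An `Hrf`.
#' @export
setGeneric("hrfKernel", function(x) standardGeneric("hrfKernel"))

#' @rdname canonicalHrf
#' @export
setMethod("hrfKernel", "Hrf", function(x) x@kernel)

setMethod("show", "Hrf", function(object) {
  cat(sprintf("Hrf: %d samples, peak lag %d volumes, sum %.4f\n",
              length(object@kernel), object@lagVolumes, sum(object@kernel)))
})

# causal discrete convolution of x with kernel, truncated to length(x)
convolveCausal <- function(x, kernel) {
  n <- length(x)
  out <- convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out[abs(out) < 1e-12] <- 0
  out
}
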