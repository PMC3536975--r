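#' Initialize streaming GLM sufficient statistics
#'
#' The incremental GLM accumulates X'X, X'y and y'y with every new
#' volume, so coefficient estimates, residual sums of squares and
#' contrast t maps can be produced at any time without storing the
#' series. The accumulators are exactly equivalent to a from-scratch
#' batch least-squares fit on the same data.
#'
#' @param nVoxels Number of voxels tracked.
#' @param regressorNames Design column names (default the five-column
#'   attention + drift design).
#' @return A [GlmState-class] with zeroed accumulators.
#' @export
glmState <- function(nVoxels,
                     regressorNames = c(DIRECTIONS, "drift")) {
  p <- length(regressorNames)
  new("GlmState",
      nSeen = 0L,
      xtx = matrix(0, p, p, dimnames = list(regressorNames, regressorNames)),
      xty = matrix(0, p, nVoxels),
      yty = numeric(nVoxels),
      regressorNames = regressorNames)
}

#' Rank-1 update of the streaming GLM
#'
#' @param state A [GlmState-class].
#' @param designRow Length-p design values for the new volume.
#' @param voxelValues Per-voxel intensities of the new volume.
#' @return The updated [GlmState-class].
#' @export
glmUpdate <- function(state, designRow, voxelValues) {
  stopifnot(is(state, "GlmState"))
  p <- length(state@regressorNames)
  if (length(designRow) != p) stop("design row has wrong length", call. = FALSE)
  if (length(voxelValues) != ncol(state@xty)) {
    stop("voxel count changed between updates", call. = FALSE)
  }
  if (!all(is.finite(designRow)) || !all(is.finite(voxelValues))) {
    stop("non-finite values in GLM update", call. = FALSE)
  }
  d <- as.numeric(designRow)
  state@xtx <- state@xtx + tcrossprod(d)
  state@xty <- state@xty + outer(d, as.numeric(voxelValues))
  state@yty <- state@yty + as.numeric(voxelValues)^2
  state@nSeen <- state@nSeen + 1L
  state
}

#' @rdname glmUpdate
#' @param x A `GlmState`.
#' @export
setGeneric("volumesSeen", function(x) standardGeneric("volumesSeen"))

#' @rdname glmUpdate
#' @export
setMethod("volumesSeen", "GlmState", function(x) x@nSeen)

setMethod("show", "GlmState", function(object) {
  cat(sprintf("GlmState: %d volumes seen, %d regressors, %d voxels\n",
              object@nSeen, length(object@regressorNames), ncol(object@xty)))
})

# solve the accumulated normal equations; pseudo-inverse fallback with a
# warning when the design is rank deficient
glmSolve <- function(state) {
  xtxInv <- tryCatch(chol2inv(chol(state@xtx)), error = function(e) NULL)
  if (is.null(xtxInv)) {
    warning("design cross-product is singular; using pseudo-inverse")
    s <- svd(state@xtx)
    pos <- s$d > max(s$d) * 1e-12
    xtxInv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  beta <- xtxInv %*% state@xty
  rss <- pmax(state@yty - colSums(state@xty * beta), 0)
  list(beta = beta, rss = rss, xtxInv = xtxInv)
}

#' GLM coefficients and residuals from the accumulators
#'
#' @param state A [GlmState-class].
#' @return List with `beta` (p x V), `rss` (length V), `dof`
#'   (`nSeen - p`).
#' @export
glmFit <- function(state) {
  stopifnot(is(state, "GlmState"))
  sol <- glmSolve(state)
  list(beta = sol$beta, rss = sol$rss,
       dof = state@nSeen - length(state@regressorNames))
}

#' The four one-versus-rest attention contrasts
#'
#' For each direction the contrast weighs that direction +1 against the
#' mean of the other three (-1/3 each); the drift weight is 0. For
#' RIGHT: (1, -1/3, -1/3, -1/3, 0).
#'
#' @return Named list of four [Contrast-class] objects (RIGHT, LEFT,
#'   UP, CENTER).
#' @export
standardContrasts <- function() {
  out <- lapply(DIRECTIONS, function(d) {
    w <- ifelse(DIRECTIONS == d, 1, -1 / 3)
    new("Contrast", name = d, weights = setNames(c(w, 0), c(DIRECTIONS, "drift")))
  })
  setNames(out, DIRECTIONS)
}

#' Contrast t map from the streaming GLM
#'
#' Computes t = (w'beta) / sqrt((rss/dof) * w'(X'X)^-1 w) per voxel.
#' Voxels with exactly zero residual variance map to a +/-Inf sentinel
#' matching the sign of the contrast estimate (0 when the estimate is
#' also 0).
#'
#' @param state A [GlmState-class] with `nSeen > p`.
#' @param contrast A [Contrast-class].
#' @return Numeric vector of per-voxel t values.
#' @export
tMap <- function(state, contrast) {
  stopifnot(is(state, "GlmState"), is(contrast, "Contrast"))
  p <- length(state@regressorNames)
  dof <- state@nSeen - p
  if (dof < 1L) stop("not enough volumes for a t map (dof < 1)", call. = FALSE)
  w <- contrast@weights
  if (all(w == 0)) return(numeric(ncol(state@xty)))
  sol <- glmSolve(state)
  est <- as.numeric(w %*% sol$beta)
  varScale <- as.numeric(t(w) %*% sol$xtxInv %*% w)
  se <- sqrt(sol$rss / dof * varScale)
  tt <- ifelse(se > 0, est / se, sign(est) * Inf)
  tt[se == 0 & est == 0] <- 0
  tt
}

#' Write a t map as 3D NIfTI
#'
#' @param tValues Per-voxel t values (length `prod(dims)`).
#' @param dims Volume grid dimensions.
#' @param path Output path.
#' @param voxelMm Voxel size for the header.
#' @export
writeTMap <- function(tValues, dims, path, voxelMm = c(1, 1, 1)) {
  vol <- array(tValues, dim = dims)
  writeVolume3d(vol, path, voxelMm = voxelMm)
  invisible(path)
}
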