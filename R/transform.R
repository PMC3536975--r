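#' Construct a rigid-body transform
#'
#' @param rotation 3 Euler angles in radians (applied as Rz Ry Rx about
#'   `center`).
#' @param translation 3 offsets in mm.
#' @param center Rotation center in mm; defaults to the volume center
#'   when applied through [registerVolume()]/[resampleVolume()].
#' @return A [RigidTransform-class].
#' @examples
#' identityTransform()
#' @export
rigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' @rdname rigidTransform
#' @export
identityTransform <- function(center = c(0, 0, 0)) {
  rigidTransform(center = center)
}

#' @rdname rigidTransform
#' @param x A `RigidTransform`.
#' @export
setGeneric("transformParameters", function(x) standardGeneric("transformParameters"))

#' @rdname rigidTransform
#' @export
setMethod("transformParameters", "RigidTransform", function(x) {
  setNames(c(x@rotation, x@translation),
           c("rx", "ry", "rz", "tx", "ty", "tz"))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rot (%s) rad, trans (%s) mm\n",
              paste(format(object@rotation, digits = 4), collapse = ", "),
              paste(format(object@translation, digits = 4), collapse = ", ")))
})

rotationMatrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Euler angles (Rz Ry Rx order) from a rotation matrix; valid away from
# the |pitch| = 90 deg singularity, more than enough for head motion.
eulerFromMatrix <- function(R) {
  b <- -asin(max(-1, min(1, R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c)
}

# derivative of the rotation matrix w.r.t. each Euler angle
rotationMatrixGrad <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  dx <- rbind(c(0, 0, 0), c(0, -sin(a), -cos(a)), c(0, cos(a), -sin(a)))
  dy <- rbind(c(-sin(b), 0, cos(b)), c(0, 0, 0), c(-cos(b), 0, -sin(b)))
  dz <- rbind(c(-sin(c), -cos(c), 0), c(cos(c), -sin(c), 0), c(0, 0, 0))
  list(rz %*% ry %*% dx, rz %*% dy %*% rx, dz %*% ry %*% rx)
}

# apply T(x) = R (x - c) + c + t to an n x 3 matrix of world points
applyTransform <- function(transform, pts) {
  R <- rotationMatrix(transform@rotation)
  ctr <- transform@center
  sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + transform@translation, "+")
}

#' Invert a rigid transform
#'
#' @param transform A [RigidTransform-class].
#' @return The inverse transform (same rotation center).
#' @export
invertTransform <- function(transform) {
  R <- rotationMatrix(transform@rotation)
  Rinv <- t(R)
  # inverse: y -> Rinv (y - c - t) + c = Rinv (y - c) + c + [Rinv(-t) ... ]
  tInv <- as.numeric(-Rinv %*% transform@translation)
  rigidTransform(rotation = eulerFromMatrix(Rinv), translation = tInv,
                 center = transform@center)
}

# world-space center of a voxel grid (0-based index convention:
# world = index * voxelMm)
worldCenter <- function(dims, voxelMm) {
  (dims - 1) / 2 * voxelMm
}
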