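#' Unit quaternion construction
#'
#' Quaternions are stored scalar-first as `(w, x, y, z)`, the order in which
#' the orientation sensors emit them. The package works in a right-handed
#' frame with x forward (walking direction), y up and z lateral (to the
#' subject's right); at rest every limb segment points straight down along
#' `(0, -1, 0)`.
#'
#' @param w,x,y,z real quaternion components (scalar first).
#' @return An object of class `"quaternion"` (a named numeric vector of
#'   length 4). Not normalised; see [quat_normalize()].
#' @seealso [quat_rotate()], [sagittal_angle()]
#' @export
#' @examples
#' q <- quaternion(1, 0, 0, 0)   # identity rotation
#' quat_rotate(q, c(0, -1, 0))
quaternion <- function(w, x, y, z) {
  q <- c(w = as.numeric(w)[1], x = as.numeric(x)[1],
         y = as.numeric(y)[1], z = as.numeric(z)[1])
  if (any(!is.finite(q))) {
    stop_validation("quaternion components must be finite numbers")
  }
  class(q) <- "quaternion"
  q
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("<quaternion> w=%.6f x=%.6f y=%.6f z=%.6f (norm %.6f)\n",
              x[1], x[2], x[3], x[4], quat_norm(x)))
  invisible(x)
}

#' Quaternion norm
#' @param q a [quaternion()].
#' @return Euclidean norm of the four components.
#' @export
quat_norm <- function(q) sqrt(sum(unclass(q)^2))

#' Normalise a quaternion to unit norm
#'
#' @param q a [quaternion()] with nonzero norm.
#' @return Unit quaternion representing the same rotation.
#' @export
quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (!is.finite(n) || n < 1e-12) {
    stop_validation("degenerate quaternion: zero norm cannot be normalised",
                    extra_class = "gaitq_degenerate_quaternion")
  }
  quaternion(q[1] / n, q[2] / n, q[3] / n, q[4] / n)
}

#' Quaternion conjugate
#' @param q a [quaternion()].
#' @return The conjugate `(w, -x, -y, -z)`; for unit quaternions, the
#'   inverse rotation.
#' @export
quat_conjugate <- function(q) quaternion(q[1], -q[2], -q[3], -q[4])

#' Hamilton product of two quaternions
#'
#' Composition `quat_multiply(a, b)` applies rotation `b` first, then `a`.
#'
#' @param a,b quaternions.
#' @return The product quaternion.
#' @export
quat_multiply <- function(a, b) {
  quaternion(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

check_unit <- function(q, tol = 1e-6) {
  if (abs(quat_norm(q) - 1) > tol) {
    stop_validation("quaternion is not unit-norm (|q| = %.8f); normalise first",
                    quat_norm(q))
  }
  invisible(q)
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Applies the quaternion sandwich product `q v q*`, the rotation used to
#' orient every limb segment of the body model.
#'
#' @param q a unit [quaternion()] (checked to 1e-6).
#' @param v numeric length-3 vector `(x, y, z)` in metres.
#' @return The rotated vector; its norm equals `|v|` to machine precision.
#' @export
quat_rotate <- function(q, v) {
  check_unit(q)
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v))) {
    stop_validation("v must be a finite numeric vector of length 3")
  }
  qv <- unclass(q)[2:4]
  t2 <- 2 * c(qv[2] * v[3] - qv[3] * v[2],
              qv[3] * v[1] - qv[1] * v[3],
              qv[1] * v[2] - qv[2] * v[1])
  unname(v + q[1] * t2 + c(qv[2] * t2[3] - qv[3] * t2[2],
                           qv[3] * t2[1] - qv[1] * t2[3],
                           qv[1] * t2[2] - qv[2] * t2[1]))
}

#' Relative rotation between two segment orientations
#'
#' Returns the rotation carrying the parent segment's orientation onto the
#' child's, `conj(q_parent) * q_child`; used for joint angles between
#' adjacent segments.
#'
#' @param q_parent,q_child unit quaternions.
#' @return Unit quaternion; identity (up to sign) when the inputs coincide.
#' @export
quat_relative <- function(q_parent, q_child) {
  check_unit(q_parent)
  check_unit(q_child)
  quat_multiply(quat_conjugate(q_parent), q_child)
}

#' Axis-angle quaternion
#'
#' @param axis numeric length-3 rotation axis (normalised internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return Unit [quaternion()].
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop_validation("rotation axis must be nonzero")
  axis <- axis / n
  half <- angle_deg * pi / 360
  quaternion(cos(half), sin(half) * axis[1], sin(half) * axis[2],
             sin(half) * axis[3])
}

#' Sagittal-plane angle of a segment orientation
#'
#' Rotates the rest direction `(0, -1, 0)` by `q`, projects the result onto
#' the sagittal (x-y) plane and returns the signed angle from the rest
#' direction, positive when the segment tilts forward. This is the angle
#' signal from which gait events (heel contact at maxima, toe-off at minima)
#' are detected.
#'
#' @param q a unit [quaternion()].
#' @return Signed angle in degrees in `(-180, 180]`, or `NA` when the
#'   segment points (near-)laterally so the sagittal projection is
#'   degenerate.
#' @export
sagittal_angle <- function(q) {
  u <- quat_rotate(q, c(0, -1, 0))
  r <- sqrt(u[1]^2 + u[2]^2)
  if (r < 1e-8) return(NA_real_)
  atan2(u[1], -u[2]) * 180 / pi
}

# Vectorised helpers on n x 4 quaternion matrices (rows may contain NA for
# missing sensor samples). Used by angle_series and the simulator so that
# per-frame work stays out of R loops.

# direction of the rotated rest vector (0,-1,0): returns n x 3 matrix
rotated_down_mat <- function(qm) {
  w <- qm[, 1]; x <- qm[, 2]; y <- qm[, 3]; z <- qm[, 4]
  cbind(2 * (w * z - x * y),
        2 * (x * x + z * z) - 1,
        -2 * (w * x + y * z))
}

sagittal_angle_mat <- function(qm) {
  u <- rotated_down_mat(qm)
  r <- sqrt(u[, 1]^2 + u[, 2]^2)
  ang <- atan2(u[, 1], -u[, 2]) * 180 / pi
  ang[!is.na(r) & r < 1e-8] <- NA_real_
  ang
}
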