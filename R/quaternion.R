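# Quaternion algebra used throughout the orientation chain.
#
# Convention (used everywhere in the package): Hamilton product, scalar-first
# storage c(w, x, y, z). A unit quaternion q mapping the sensor frame (SF) to
# the global frame (GF) acts on a sensor-frame vector v by q %q% v %q% q^-1,
# which is an *active* right-handed rotation: quat_from_axis_angle(Z, pi/2)
# takes X to Y.

#' Construct a quaternion
#'
#' @param w Scalar part.
#' @param x,y,z Vector part.
#' @return Numeric vector `c(w, x, y, z)` of class `"quaternion"`.
#' @export
quaternion <- function(w, x = 0, y = 0, z = 0) {
  q <- c(w, x, y, z)
  stopifnot(length(q) == 4L, all(is.finite(q)))
  structure(q, class = "quaternion")
}

#' Identity quaternion
#' @return The identity rotation `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() quaternion(1, 0, 0, 0)

#' Quaternion norm
#' @param q Quaternion.
#' @return Euclidean norm of the 4-vector.
#' @export
quat_norm <- function(q) sqrt(sum(unclass(q)^2))

#' Normalize a quaternion to unit norm
#' @param q Quaternion.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (n == 0) stop("cannot normalize a zero quaternion")
  structure(unclass(q) / n, class = "quaternion")
}

#' Quaternion conjugate
#' @param q Quaternion.
#' @return Conjugate (inverse for unit quaternions).
#' @export
quat_conjugate <- function(q) {
  structure(c(q[1], -q[2], -q[3], -q[4]), class = "quaternion")
}

#' Quaternion inverse
#' @param q Quaternion (need not be unit norm).
#' @return Inverse such that `quat_multiply(q, quat_inverse(q))` is identity.
#' @export
quat_inverse <- function(q) {
  n2 <- sum(unclass(q)^2)
  if (n2 == 0) stop("cannot invert a zero quaternion")
  structure(c(q[1], -q[2], -q[3], -q[4]) / n2, class = "quaternion")
}

#' Hamilton product of two quaternions
#' @param p,q Quaternions.
#' @return `p` composed with `q` (apply `q` first when both are rotations
#'   acting by conjugation).
#' @export
quat_multiply <- function(p, q) {
  structure(c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  ), class = "quaternion")
}

#' Quaternion from axis and angle
#'
#' @param axis Rotation axis, 3-vector (normalized internally).
#' @param angle Rotation angle in radians (right-handed about `axis`).
#' @return Unit quaternion. A zero axis with zero angle gives the identity.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) {
    if (abs(angle) > 0) stop("zero axis with nonzero angle")
    return(quat_identity())
  }
  u <- axis / n
  structure(c(cos(angle / 2), u * sin(angle / 2)), class = "quaternion")
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix R with `R %*% v == quat_rotate(q, v)`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a 3-vector by a unit quaternion
#' @param q Unit quaternion.
#' @param v 3-vector.
#' @return Rotated 3-vector `q v q^-1`.
#' @export
quat_rotate <- function(q, v) {
  u <- c(q[2], q[3], q[4])
  w <- q[1]
  uv <- pracma::cross(u, v)
  v + 2 * (w * uv + pracma::cross(u, uv))
}

#' Angle between two unit quaternions
#' @param p,q Unit quaternions.
#' @return Rotation angle (radians, in `[0, pi]`) of `p^-1 q`, i.e. how far the
#'   two orientations are apart; insensitive to the q/-q double cover.
#' @export
quat_angle_between <- function(p, q) {
  d <- abs(sum(unclass(p) * unclass(q)))
  2 * acos(min(1, d))
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("quaternion [w=% .6f, x=% .6f, y=% .6f, z=% .6f] |q|=%.9f\n",
              x[1], x[2], x[3], x[4], quat_norm(x)))
  invisible(x)
}

# ---- row-wise operations on n x 4 quaternion matrices -----------------------
# The 500 Hz series make per-sample R-level calls too slow; these vectorized
# forms operate on whole series at once.

# Row-wise Hamilton product of n x 4 matrices P and Q.
quat_multiply_rows <- function(P, Q) {
  cbind(
    P[, 1] * Q[, 1] - P[, 2] * Q[, 2] - P[, 3] * Q[, 3] - P[, 4] * Q[, 4],
    P[, 1] * Q[, 2] + P[, 2] * Q[, 1] + P[, 3] * Q[, 4] - P[, 4] * Q[, 3],
    P[, 1] * Q[, 3] - P[, 2] * Q[, 4] + P[, 3] * Q[, 1] + P[, 4] * Q[, 2],
    P[, 1] * Q[, 4] + P[, 2] * Q[, 3] - P[, 3] * Q[, 2] + P[, 4] * Q[, 1]
  )
}

# Rotate the rows of an n x 3 matrix V by the corresponding rows of the
# n x 4 unit-quaternion matrix Q: out[i, ] = Q[i] V[i] Q[i]^-1.
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1]; ux <- Q[, 2]; uy <- Q[, 3]; uz <- Q[, 4]
  vx <- V[, 1]; vy <- V[, 2]; vz <- V[, 3]
  # t = 2 (u x v)
  tx <- 2 * (uy * vz - uz * vy)
  ty <- 2 * (uz * vx - ux * vz)
  tz <- 2 * (ux * vy - uy * vx)
  # v' = v + w t + u x t
  cbind(
    vx + w * tx + uy * tz - uz * ty,
    vy + w * ty + uz * tx - ux * tz,
    vz + w * tz + ux * ty - uy * tx
  )
}

# Row-wise renormalization of an n x 4 quaternion matrix.
quat_normalize_rows <- function(Q) {
  Q / sqrt(rowSums(Q^2))
}
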