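#' Quaternion primitives
#'
#' Attitude is represented as a unit quaternion `c(q1, q2, q3, q4)` with the
#' scalar part first (`q1`), so the identity rotation is `c(1, 0, 0, 0)`.
#' These helpers underpin the orientation filter and the inverse sensor model
#' of the simulator.
#'
#' @param q,a,b Numeric vectors of length 4, scalar part first.
#' @return A numeric vector of length 4.
#' @name quaternion
NULL

#' @rdname quaternion
#' @details `quat_normalize()` rescales to unit Euclidean norm and errors on a
#'   zero-norm (or non-finite) input, which carries no direction information.
#' @examples
#' quat_normalize(c(2, 0, 0, 0))
#' quat_multiply(quat_axis_angle(c(0, 0, 1), 45), quat_axis_angle(c(0, 0, 1), 45))
#' @export
quat_normalize <- function(q) {
  check_quat(q)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || n <= 0) {
    abort("Cannot normalize a zero-norm quaternion.", class = "trunkdx_invalid_quaternion")
  }
  q / n
}

#' @rdname quaternion
#' @details `quat_multiply()` is the Hamilton product; composition of rotations
#'   `a` then applied to `b`'s frame follows the usual convention
#'   `q_total = a %q% b`.
#' @export
quat_multiply <- function(a, b) {
  check_quat(a)
  check_quat(b)
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' @rdname quaternion
#' @export
quat_conjugate <- function(q) {
  check_quat(q)
  c(q[1], -q[2], -q[3], -q[4])
}

#' @rdname quaternion
#' @param axis Numeric length-3 rotation axis (need not be unit norm).
#' @param angle_deg Rotation angle in degrees, right-handed about `axis`.
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, all(is.finite(axis)), is.finite(angle_deg))
  n <- sqrt(sum(axis^2))
  if (n <= 0) abort("Rotation axis must be non-zero.", class = "trunkdx_invalid_quaternion")
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

#' Rotation matrix of a unit quaternion
#'
#' Returns the 3x3 direction cosine matrix mapping sensor-frame vectors into
#' the Earth frame (`v_earth = R %*% v_sensor`). Used as an independent oracle
#' in tests and by the inverse sensor model.
#'
#' @param q Unit quaternion, scalar first.
#' @return A 3x3 numeric matrix.
#' @export
quat_to_matrix <- function(q) {
  check_quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a quaternion to aerospace Euler angles
#'
#' Uses the Z-Y-X (yaw-pitch-roll) sequence: yaw about the Earth Z axis, then
#' pitch about the intermediate Y axis, then roll about the body X axis. The
#' arcsine argument for pitch is clamped to `[-1, 1]` so near-gimbal-lock
#' inputs degrade gracefully instead of producing `NaN`.
#'
#' @param q Unit quaternion, scalar first.
#' @return Named numeric vector `c(yaw, pitch, roll)` in degrees, with
#'   yaw/roll in `(-180, 180]` and pitch in `[-90, 90]`.
#' @examples
#' quat_to_euler(c(1, 0, 0, 0))
#' quat_to_euler(euler_to_quat(10, 20, 30))
#' @export
quat_to_euler <- function(q) {
  check_quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  yaw <- atan2(2 * (x * y + w * z), 1 - 2 * (y^2 + z^2))
  s <- 2 * (w * y - x * z)
  pitch <- asin(min(1, max(-1, s)))
  roll <- atan2(2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  r <- c(yaw, pitch, roll) * 180 / pi
  # map -180 to +180 so yaw/roll live in (-180, 180]
  r[c(1, 3)] <- ifelse(r[c(1, 3)] <= -180, r[c(1, 3)] + 360, r[c(1, 3)])
  setNames(r, c("yaw", "pitch", "roll"))
}

#' Convert aerospace Euler angles to a unit quaternion
#'
#' Inverse of [quat_to_euler()] away from gimbal lock (|pitch| = 90 degrees).
#'
#' @param yaw,pitch,roll Angles in degrees (Z-Y-X sequence).
#' @return Unit quaternion, scalar first.
#' @export
euler_to_quat <- function(yaw, pitch, roll) {
  stopifnot(is.finite(yaw), is.finite(pitch), is.finite(roll))
  qz <- quat_axis_angle(c(0, 0, 1), yaw)
  qy <- quat_axis_angle(c(0, 1, 0), pitch)
  qx <- quat_axis_angle(c(1, 0, 0), roll)
  quat_normalize(quat_multiply(quat_multiply(qz, qy), qx))
}

check_quat <- function(q) {
  if (!is.numeric(q) || length(q) != 4 || anyNA(q) || any(!is.finite(q))) {
    abort("A quaternion must be a finite numeric vector of length 4.",
      class = "trunkdx_invalid_quaternion"
    )
  }
  invisible(q)
}
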