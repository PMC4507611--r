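#' Orientation filter configuration
#'
#' Settings for the gradient-descent quaternion fusion filter. `beta` trades
#' gyroscope trust against the accelerometer/magnetometer correction: 0 gives
#' pure gyro integration, larger values converge faster to the field
#' directions but admit more measurement noise. The default sampling rate
#' matches the wearable units used for trunk assessment (51.2 Hz).
#'
#' @param beta Non-negative gradient step gain (dimensionless). Default 0.1.
#' @param sample_rate Nominal sampling rate in Hz, used when timestamps are
#'   unavailable. Default 51.2.
#' @param use_magnetometer Should the magnetometer correct heading? Roll and
#'   pitch — hence the trunk angle — are unaffected either way.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(beta = 0.1, sample_rate = 51.2, use_magnetometer = TRUE) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1, sample_rate > 0)
  structure(
    list(
      beta = beta, sample_rate = sample_rate,
      use_magnetometer = isTRUE(use_magnetometer)
    ),
    class = "filter_config"
  )
}

#' One step of gradient-descent sensor fusion
#'
#' Advances the attitude quaternion by one sample: the quaternion derivative
#' from the gyroscope rate is blended with a normalized gradient-descent step
#' that pulls the estimate toward the measured gravity direction (and, when
#' enabled and available, the magnetic field direction), scaled by
#' `cfg$beta`. Accelerometer magnitude is irrelevant — only the direction is
#' used — so the filter is invariant to accel rescaling.
#'
#' A non-finite or zero-norm accelerometer sample disables the corrective
#' step for that update (gyro integration still runs); the same applies to
#' the magnetometer.
#'
#' @param state Current unit quaternion (scalar first).
#' @param accel Length-3 accelerometer sample, m/s^2.
#' @param gyro Length-3 gyroscope sample, rad/s.
#' @param mag Optional length-3 magnetometer sample (consistent arbitrary
#'   units), or `NULL`.
#' @param cfg A [filter_config()].
#' @param dt Time step in seconds (> 0).
#' @return The updated unit quaternion.
#' @export
fusion_update <- function(state, accel, gyro, mag = NULL, cfg = filter_config(), dt = 1 / cfg$sample_rate) {
  check_quat(state)
  stopifnot(length(accel) == 3, length(gyro) == 3, is.finite(dt), dt > 0)
  if (anyNA(gyro) || any(!is.finite(gyro))) {
    abort("Gyroscope sample must be finite.", class = "trunkdx_invalid_sample")
  }
  q <- state
  qdot <- 0.5 * quat_multiply(q, c(0, gyro))

  grad <- NULL
  a_ok <- !anyNA(accel) && all(is.finite(accel)) && sum(accel^2) > 0
  if (cfg$beta > 0 && a_ok) {
    a <- accel / sqrt(sum(accel^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    # gravity objective: predicted sensor-frame up-direction minus measured
    f <- c(
      2 * (x * z - w * y) - a[1],
      2 * (w * x + y * z) - a[2],
      2 * (0.5 - x^2 - y^2) - a[3]
    )
    grad <- c(
      -2 * y * f[1] + 2 * x * f[2],
      2 * z * f[1] + 2 * w * f[2] - 4 * x * f[3],
      -2 * w * f[1] + 2 * z * f[2] - 4 * y * f[3],
      2 * x * f[1] + 2 * y * f[2]
    )
    m_ok <- cfg$use_magnetometer && !is.null(mag) &&
      !anyNA(mag) && all(is.finite(mag)) && sum(mag^2) > 0
    if (m_ok) {
      m <- mag / sqrt(sum(mag^2))
      # Earth-frame field reference from the current estimate: keep the
      # horizontal magnitude and vertical component, zero the east component,
      # so the magnetometer only constrains heading.
      h <- quat_to_matrix(q) %*% m
      bx <- sqrt(h[1]^2 + h[2]^2)
      bz <- h[3]
      fm <- c(
        2 * bx * (0.5 - y^2 - z^2) + 2 * bz * (x * z - w * y) - m[1],
        2 * bx * (x * y - w * z) + 2 * bz * (w * x + y * z) - m[2],
        2 * bx * (w * y + x * z) + 2 * bz * (0.5 - x^2 - y^2) - m[3]
      )
      grad <- grad + c(
        -2 * bz * y * fm[1] + (-2 * bx * z + 2 * bz * x) * fm[2] + 2 * bx * y * fm[3],
        2 * bz * z * fm[1] + (2 * bx * y + 2 * bz * w) * fm[2] + (2 * bx * z - 4 * bz * x) * fm[3],
        (-4 * bx * y - 2 * bz * w) * fm[1] + (2 * bx * x + 2 * bz * z) * fm[2] + (2 * bx * w - 4 * bz * y) * fm[3],
        (-4 * bx * z + 2 * bz * x) * fm[1] + (-2 * bx * w + 2 * bz * y) * fm[2] + 2 * bx * x * fm[3]
      )
    }
    gn <- sqrt(sum(grad^2))
    if (gn > 0) {
      qdot <- qdot - cfg$beta * grad / gn
    }
  }
  quat_normalize(q + qdot * dt)
}

#' Estimate an orientation stream from IMU samples
#'
#' Runs the fusion filter over a time-ordered IMU stream and returns the
#' Euler-angle trajectory. `dt` is taken from consecutive timestamps, falling
#' back to `1 / cfg$sample_rate` for the first sample or any non-positive
#' timestamp difference.
#'
#' @param data A data frame with columns `t, ax, ay, az, gx, gy, gz` and
#'   optionally `mx, my, mz` (see [read_imu_stream()] for units).
#' @param cfg A [filter_config()].
#' @param q0 Initial attitude quaternion; defaults to the identity.
#' @return A tibble with columns `t`, `yaw_deg`, `pitch_deg`, `roll_deg`.
#' @seealso [trunk_angle_stream()] for the roll-only trace used by the
#'   endurance tests.
#' @export
orientation_stream <- function(data, cfg = filter_config(), q0 = c(1, 0, 0, 0)) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("IMU stream must be a data frame with at least one sample.",
      class = "trunkdx_empty_input"
    )
  }
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("IMU stream is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "trunkdx_format_error"
    )
  }
  has_mag <- all(c("mx", "my", "mz") %in% names(data))
  t <- data$t
  if (any(diff(t) < 0)) {
    abort("IMU timestamps must be non-decreasing; see read_imu_stream() for sorting.",
      class = "trunkdx_format_error"
    )
  }
  n <- nrow(data)
  q <- quat_normalize(q0)
  out <- matrix(NA_real_, nrow = n, ncol = 3)
  dt0 <- 1 / cfg$sample_rate
  for (i in seq_len(n)) {
    dt <- if (i == 1) dt0 else t[i] - t[i - 1]
    if (!is.finite(dt) || dt <= 0) dt <- dt0
    mag <- if (has_mag) c(data$mx[i], data$my[i], data$mz[i]) else NULL
    q <- fusion_update(
      q,
      accel = c(data$ax[i], data$ay[i], data$az[i]),
      gyro = c(data$gx[i], data$gy[i], data$gz[i]),
      mag = mag, cfg = cfg, dt = dt
    )
    out[i, ] <- quat_to_euler(q)
  }
  tibble::tibble(
    t = t, yaw_deg = out[, 1], pitch_deg = out[, 2], roll_deg = out[, 3]
  )
}

#' Trunk angle trace from an IMU stream
#'
#' The roll angle of the fused attitude represents the trunk angle in all
#' supported endurance tests (the sensor is mounted so that posture droop
#' appears as roll). This is a thin wrapper over [orientation_stream()]
#' returning the `(t, roll_deg)` trace consumed by [run_attempt()] and
#' [run_test()].
#'
#' @inheritParams orientation_stream
#' @return A tibble with columns `t` and `roll_deg`.
#' @export
trunk_angle_stream <- function(data, cfg = filter_config(), q0 = c(1, 0, 0, 0)) {
  es <- orientation_stream(data, cfg = cfg, q0 = q0)
  dplyr::select(es, "t", "roll_deg")
}
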