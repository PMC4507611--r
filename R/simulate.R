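#' Posture-hold scenario
#'
#' Ground-truth description of a simulated endurance attempt: the subject
#' holds `initial_roll` (with Gaussian postural tremor of SD `tremor_sd`)
#' for `hold_duration` seconds, then the posture droops linearly at
#' `droop_rate` degrees per second. With zero tremor the trunk angle first
#' strictly exceeds a droop tolerance `tol` at
#' `hold_duration + tol / droop_rate` seconds — the analytic crossing time
#' used as the oracle for the session state machine.
#'
#' @param initial_roll Held trunk angle, degrees.
#' @param hold_duration Steady hold before droop onset, seconds (>= 0).
#' @param droop_rate Droop rate after onset, degrees/s (>= 0).
#' @param tremor_sd SD of per-sample postural tremor, degrees.
#' @param seed Integer seed; generation is reproducible per scenario.
#' @return A list of class `posture_scenario`.
#' @export
posture_scenario <- function(initial_roll = 0, hold_duration = 60, droop_rate = 5,
                             tremor_sd = 0, seed = 1) {
  stopifnot(hold_duration >= 0, droop_rate >= 0, tremor_sd >= 0)
  structure(
    list(
      initial_roll = initial_roll, hold_duration = hold_duration,
      droop_rate = droop_rate, tremor_sd = tremor_sd, seed = as.integer(seed)
    ),
    class = "posture_scenario"
  )
}

#' Simulate a ground-truth orientation trajectory
#'
#' @param scenario A [posture_scenario()].
#' @param sample_rate Sampling rate, Hz.
#' @param duration Total trace length in seconds; defaults to the hold plus
#'   enough droop to cross a 30-degree deviation (or 10 s when the droop
#'   rate is zero).
#' @return A tibble `t`, `yaw_deg`, `pitch_deg`, `roll_deg`; yaw and pitch
#'   carry the same small tremor as roll.
#' @export
simulate_trajectory <- function(scenario, sample_rate = 51.2, duration = NULL) {
  stopifnot(inherits(scenario, "posture_scenario"), sample_rate > 0)
  if (is.null(duration)) {
    duration <- scenario$hold_duration +
      if (scenario$droop_rate > 0) 35 / scenario$droop_rate else 10
  }
  t <- seq(0, duration, by = 1 / sample_rate)
  n <- length(t)
  droop <- pmax(0, t - scenario$hold_duration) * scenario$droop_rate
  with_seed(scenario$seed, {
    tremor <- if (scenario$tremor_sd > 0) rnorm(n, 0, scenario$tremor_sd) else numeric(n)
    yp <- if (scenario$tremor_sd > 0) {
      matrix(rnorm(2 * n, 0, scenario$tremor_sd), ncol = 2)
    } else {
      matrix(0, n, 2)
    }
    tibble::tibble(
      t = t,
      yaw_deg = yp[, 1],
      pitch_deg = yp[, 2],
      roll_deg = scenario$initial_roll + droop + tremor
    )
  })
}

#' Inverse IMU sensor model
#'
#' Synthesizes raw IMU samples from an orientation trajectory: the
#' accelerometer reads the attitude-rotated gravity reaction (magnitude
#' 9.80665 m/s^2), the gyroscope the finite-difference body angular rate,
#' and the magnetometer the attitude-rotated Earth field (unit-norm vector
#' with 50-degree downward inclination). Independent Gaussian noise is added
#' per axis.
#'
#' @param trajectory Tibble from [simulate_trajectory()] (`t`, `yaw_deg`,
#'   `pitch_deg`, `roll_deg`).
#' @param accel_noise_sd,gyro_noise_sd,mag_noise_sd Noise SDs in m/s^2,
#'   rad/s and field units.
#' @param seed Integer seed for the noise draws.
#' @return A tibble with columns `t, ax, ay, az, gx, gy, gz, mx, my, mz`.
#' @export
synthesize_imu <- function(trajectory, accel_noise_sd = 0.05, gyro_noise_sd = 0.005,
                           mag_noise_sd = 0.01, seed = 1) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0) {
    abort("Trajectory must be a non-empty data frame.", class = "trunkdx_empty_input")
  }
  n <- nrow(trajectory)
  g <- 9.80665
  incl <- 50 * pi / 180
  m_earth <- c(cos(incl), 0, -sin(incl))
  quats <- purrr::pmap(
    list(trajectory$yaw_deg, trajectory$pitch_deg, trajectory$roll_deg),
    euler_to_quat
  )
  accel <- matrix(NA_real_, n, 3)
  gyro <- matrix(0, n, 3)
  mag <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    Rt <- t(quat_to_matrix(quats[[i]]))
    accel[i, ] <- Rt %*% c(0, 0, g)
    mag[i, ] <- Rt %*% m_earth
    if (i < n) {
      dt <- trajectory$t[i + 1] - trajectory$t[i]
      dq <- quat_multiply(quat_conjugate(quats[[i]]), quats[[i + 1]])
      if (dq[1] < 0) dq <- -dq
      vnorm <- sqrt(sum(dq[2:4]^2))
      if (vnorm > 0 && dt > 0) {
        angle <- 2 * atan2(vnorm, dq[1])
        gyro[i, ] <- dq[2:4] / vnorm * angle / dt
      }
    }
  }
  if (n > 1) gyro[n, ] <- gyro[n - 1, ]
  with_seed(seed, {
    if (accel_noise_sd > 0) accel <- accel + rnorm(3 * n, 0, accel_noise_sd)
    if (gyro_noise_sd > 0) gyro <- gyro + rnorm(3 * n, 0, gyro_noise_sd)
    if (mag_noise_sd > 0) mag <- mag + rnorm(3 * n, 0, mag_noise_sd)
    tibble::tibble(
      t = trajectory$t,
      ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
      gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
      mx = mag[, 1], my = mag[, 2], mz = mag[, 3]
    )
  })
}

#' EMG amplitude scenario
#'
#' Stochastic surface-EMG model: zero-mean Gaussian noise whose
#' instantaneous RMS amplitude is `baseline_rms + fatigue_slope * t`, i.e.
#' an amplitude-modulated process whose epoch RMS trends upward with
#' fatigue.
#'
#' @param baseline_rms Initial RMS amplitude, mV (> 0).
#' @param fatigue_slope Amplitude drift, mV/s.
#' @param seed Integer seed.
#' @return A list of class `emg_scenario`.
#' @export
emg_scenario <- function(baseline_rms = 0.1, fatigue_slope = 0, seed = 1) {
  stopifnot(baseline_rms > 0)
  structure(
    list(
      baseline_rms = baseline_rms, fatigue_slope = fatigue_slope,
      seed = as.integer(seed)
    ),
    class = "emg_scenario"
  )
}

#' Simulate an EMG stream
#'
#' @param scenario An [emg_scenario()].
#' @param duration Trace length, seconds (> 0).
#' @param sample_rate Sampling rate, Hz.
#' @return A tibble `t`, `emg_mV`.
#' @export
simulate_emg <- function(scenario, duration, sample_rate = 51.2) {
  stopifnot(inherits(scenario, "emg_scenario"), duration > 0, sample_rate > 0)
  t <- seq(0, duration, by = 1 / sample_rate)
  amp <- pmax(0, scenario$baseline_rms + scenario$fatigue_slope * t)
  with_seed(scenario$seed, {
    tibble::tibble(t = t, emg_mV = amp * rnorm(length(t)))
  })
}

#' Simulate a paired method-comparison study
#'
#' Draws `n` subjects from the one-way random model: subject true values are
#' `Normal(mean, sigma_between^2)` and each method observes the true value
#' plus independent `Normal(0, sigma_within^2)` error. The analytic
#' average-measures ICC for `k = 2`,
#' `2 sigma_between^2 / (2 sigma_between^2 + sigma_within^2)`, is attached
#' as attribute `true_icc` (and the single-measures value as
#' `true_icc_single`).
#'
#' @param n Number of subjects (>= 2).
#' @param sigma_between,sigma_within Between- and within-subject SDs,
#'   seconds (>= 0).
#' @param mean Population mean duration, seconds.
#' @param seed Integer seed.
#' @return A tibble `subject`, `method_a`, `method_b`.
#' @export
simulate_paired_study <- function(n, sigma_between, sigma_within, mean = 80, seed = 1) {
  stopifnot(n >= 2, sigma_between >= 0, sigma_within >= 0)
  out <- with_seed(seed, {
    truth <- rnorm(n, mean, sigma_between)
    tibble::tibble(
      subject = seq_len(n),
      method_a = truth + rnorm(n, 0, sigma_within),
      method_b = truth + rnorm(n, 0, sigma_within)
    )
  })
  vb <- sigma_between^2
  vw <- sigma_within^2
  attr(out, "true_icc") <- if (vb + vw == 0) NA_real_ else 2 * vb / (2 * vb + vw)
  attr(out, "true_icc_single") <- if (vb + vw == 0) NA_real_ else vb / (vb + vw)
  out
}
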