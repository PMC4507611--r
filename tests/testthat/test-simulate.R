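test_that("trajectories are deterministic per seed and follow the hold/droop law", {
  sc <- posture_scenario(initial_roll = 12, hold_duration = 20, droop_rate = 4,
                         tremor_sd = 0.3, seed = 77)
  t1 <- simulate_trajectory(sc)
  t2 <- simulate_trajectory(sc)
  expect_identical(t1, t2)

  # zero droop, zero tremor -> constant roll
  flat <- simulate_trajectory(
    posture_scenario(30, 10, 0, tremor_sd = 0, seed = 1),
    duration = 10
  )
  expect_true(all(flat$roll_deg == 30))
  expect_true(all(flat$yaw_deg == 0))

  # analytic crossing: hold 90 s at rate 20 deg/s crosses ref+10 at 90.5 s
  sc2 <- posture_scenario(0, 90, 20, tremor_sd = 0, seed = 1)
  tr <- simulate_trajectory(sc2, duration = 95)
  crossing <- min(tr$t[tr$roll_deg > 10])
  expect_equal(crossing, 90.5, tolerance = 1 / 51.2)
})

test_that("the inverse sensor model emits gravity, body rates and the Earth field", {
  flat <- simulate_trajectory(posture_scenario(0, 2, 0, 0, seed = 1), duration = 2)
  imu <- synthesize_imu(flat, accel_noise_sd = 0, gyro_noise_sd = 0, mag_noise_sd = 0)
  expect_equal(unique(round(imu$az, 9)), 9.80665)
  expect_true(all(abs(c(imu$ax, imu$ay)) < 1e-9))
  expect_true(all(abs(c(imu$gx, imu$gy, imu$gz)) < 1e-9))
  expect_equal(sqrt(imu$mx[1]^2 + imu$my[1]^2 + imu$mz[1]^2), 1, tolerance = 1e-9)

  # noise sd = 0: the seed is irrelevant
  imu2 <- synthesize_imu(flat, 0, 0, 0, seed = 999)
  expect_identical(imu, imu2)

  # constant-rate roll trajectory produces the matching gx
  ramp <- tibble::tibble(
    t = seq(0, 2, by = 1 / 51.2), yaw_deg = 0, pitch_deg = 0,
    roll_deg = seq(0, 2, by = 1 / 51.2) * 15
  )
  imu3 <- synthesize_imu(ramp, 0, 0, 0)
  expect_equal(imu3$gx, rep(15 * pi / 180, nrow(imu3)), tolerance = 1e-6)
})

test_that("fusing a noiseless synthetic stream recovers the trajectory", {
  sc <- posture_scenario(initial_roll = 25, hold_duration = 30, droop_rate = 0,
                         tremor_sd = 0, seed = 2)
  traj <- simulate_trajectory(sc, duration = 30)
  imu <- synthesize_imu(traj, 0, 0, 0)
  ang <- trunk_angle_stream(imu)
  tail_idx <- ang$t > 20
  expect_lt(max(abs(ang$roll_deg[tail_idx] - 25)), 0.5)
})

test_that("simulated EMG has the requested amplitude profile", {
  sc <- emg_scenario(baseline_rms = 0.15, fatigue_slope = 0, seed = 42)
  emg <- simulate_emg(sc, duration = 60)
  expect_identical(emg, simulate_emg(sc, duration = 60))
  m <- epoch_metrics(emg, epoch_len = 1)
  # per-epoch RMS from ~51 samples has relative SD ~ 1/sqrt(2*51) ~ 10%
  expect_true(all(abs(m$rms - 0.15) / 0.15 < 0.35))
  expect_gt(mean(abs(m$rms - 0.15) / 0.15 < 0.10), 0.5)
  expect_lt(abs(emg_rms(emg$emg_mV) - 0.15) / 0.15, 0.05)
  expect_lt(abs(mean(emg$emg_mV)), 0.01)

  # positive fatigue slope -> monotone upward trend in epoch RMS
  up <- simulate_emg(emg_scenario(0.1, 0.005, seed = 9), duration = 60)
  mu <- epoch_metrics(up, epoch_len = 1)
  tau <- stats::cor(mu$t_start, mu$rms, method = "kendall")
  expect_gt(tau, 0)
})

test_that("paired-study generator matches its analytic ICC", {
  # no within-subject error: perfect agreement
  pm <- simulate_paired_study(50, sigma_between = 10, sigma_within = 0, seed = 3)
  expect_equal(attr(pm, "true_icc"), 1)
  expect_equal(icc_oneway(pm)$estimate, 1)

  # no between-subject signal: ICC near zero
  pm0 <- simulate_paired_study(2000, sigma_between = 0, sigma_within = 5, seed = 4)
  expect_equal(attr(pm0, "true_icc"), 0)
  expect_lt(abs(icc_oneway(pm0)$estimate), 0.1)

  expect_identical(
    simulate_paired_study(20, 5, 2, seed = 8),
    simulate_paired_study(20, 5, 2, seed = 8)
  )
})

test_that("an 84 s hold flows end-to-end into a SBET 'good' result", {
  sc <- posture_scenario(initial_roll = 0, hold_duration = 84, droop_rate = 25,
                         tremor_sd = 0, seed = 6)
  stream <- truth_angle_stream(sc)
  res <- run_test(stream, "SBET_LEFT", start_times = 0)
  expect_equal(res$total_duration, 84 + 10 / 25, tolerance = 1 / 51.2)
  expect_equal(res$category, "good")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(100)
  before <- .Random.seed
  invisible(simulate_paired_study(10, 5, 2, seed = 1))
  invisible(simulate_emg(emg_scenario(seed = 2), duration = 1))
  expect_identical(.Random.seed, before)
})
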