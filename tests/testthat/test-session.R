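test_that("reference capture takes the nearest preceding sample", {
  const <- tibble::tibble(t = seq(0, 10, by = 0.1), roll_deg = 0)
  expect_equal(capture_reference(const, 4.32), 0)

  ramp <- tibble::tibble(t = seq(0, 10, by = 0.5), roll_deg = seq(0, 10, by = 0.5) * 2)
  expect_equal(capture_reference(ramp, 5), 10) # exact sample
  expect_equal(capture_reference(ramp, 5.2), 10) # nearest preceding

  expect_error(capture_reference(ramp, -1), class = "trunkdx_out_of_range")
  expect_error(capture_reference(ramp, 11), class = "trunkdx_out_of_range")
})

test_that("termination thresholds are strict and reasons prioritized", {
  # droop beyond 10 degrees ends a Sorensen attempt
  r <- check_termination("STEET", reference = 5, current = 16, elapsed = 30)
  expect_true(r$terminate)
  expect_equal(r$reason, "angle_exceeded")

  # 29 degrees of droop is within the 30-degree trunk-curl tolerance
  r <- check_termination("TCSET", reference = 60, current = 31, elapsed = 100)
  expect_false(r$terminate)

  # exactly at tolerance: continue ("more than" is strict)
  expect_false(check_termination("STEET", 0, 10, 30)$terminate)
  expect_false(check_termination("STEET", 0, -10, 30)$terminate)
  expect_false(check_termination("TCSET", 60, 30, 30)$terminate)
  expect_true(check_termination("TCSET", 60, 29.99, 30)$terminate)

  # time cap is strict at 240 s
  expect_false(check_termination("SBET_LEFT", 0, 0, 240)$terminate)
  r <- check_termination("SBET_LEFT", 0, 0, 240.02)
  expect_true(r$terminate)
  expect_equal(r$reason, "max_duration")

  # manual stop outranks a simultaneous angle breach
  r <- check_termination("STEET", 0, 50, 250, manual_stop = TRUE)
  expect_equal(r$reason, "manual_stop")
  # angle breach outranks the simultaneous time cap
  r <- check_termination("STEET", 0, 50, 250)
  expect_equal(r$reason, "angle_exceeded")
})

test_that("attempt duration matches the analytic droop crossing", {
  fs <- 51.2
  sc <- posture_scenario(initial_roll = 0, hold_duration = 90, droop_rate = 20,
                         tremor_sd = 0, seed = 1)
  stream <- truth_angle_stream(sc, duration = 95)
  a <- run_attempt(stream, "STEET", start_time = 0)
  expect_equal(a$termination_reason, "angle_exceeded")
  expect_equal(a$duration, 90.5, tolerance = 1 / fs)
  expect_equal(a$reference_angle, 0)
})

test_that("holding forever ends at the 240 s cap; instant droop gives zero", {
  hold <- tibble::tibble(t = seq(0, 245, by = 0.5), roll_deg = 0)
  a <- run_attempt(hold, "TCSET", start_time = 0)
  expect_equal(a$termination_reason, "max_duration")
  expect_equal(a$duration, 240)

  drop0 <- tibble::tibble(t = seq(0, 5, by = 1 / 51.2), roll_deg = c(0, rep(90, 256)))
  a0 <- run_attempt(drop0, "STEET", start_time = 0)
  expect_equal(a0$termination_reason, "angle_exceeded")
  expect_lte(a0$duration, 1 / 51.2)
})

test_that("a stream that ends mid-attempt raises a truncated-stream error", {
  short <- tibble::tibble(t = seq(0, 10, by = 0.5), roll_deg = 0)
  err <- tryCatch(run_attempt(short, "STEET", 0), condition = function(c) c)
  expect_s3_class(err, "trunkdx_truncated_stream")
  expect_equal(err$partial_duration, 10)
})

test_that("duration is monotone in droop onset", {
  durations <- sapply(c(10, 25, 40, 60, 80), function(h) {
    sc <- posture_scenario(initial_roll = 5, hold_duration = h, droop_rate = 8,
                           tremor_sd = 0, seed = 1)
    run_attempt(truth_angle_stream(sc), "SBET_RIGHT", 0)$duration
  })
  expect_true(all(diff(durations) > 0))
})

test_that("manual stop terminates at the stop event", {
  stream <- tibble::tibble(t = seq(0, 100, by = 1 / 51.2), roll_deg = 0)
  a <- run_attempt(stream, "STEET", start_time = 0, stop_time = 42)
  expect_equal(a$termination_reason, "manual_stop")
  expect_equal(a$duration, 42, tolerance = 1 / 51.2)
})

test_that("run_test sums Sorensen attempts and scores the total", {
  fs <- 51.2
  t <- seq(0, 400, by = 1 / fs)
  roll <- rep(0, length(t))
  # first attempt: droop of 20 deg/s starting at t = 60 -> duration 60.5
  roll[t > 60 & t <= 100] <- (t[t > 60 & t <= 100] - 60) * 20
  # second attempt starting at t = 150: droop at t = 190 -> duration 40.5
  roll[t > 190 & t <= 240] <- (t[t > 190 & t <= 240] - 190) * 20
  stream <- tibble::tibble(t = t, roll_deg = roll)
  res <- run_test(stream, "STEET", start_times = c(0, 150))
  expect_s3_class(res, "endurance_test")
  expect_equal(nrow(res$attempts), 2)
  expect_equal(res$total_duration, 101, tolerance = 2 / fs)
  expect_equal(res$category, "good")

  # example arithmetic: attempts of 60 s and 40 s total 100 s
  expect_equal(60 + 40, 100)

  # one attempt only is allowed (the second chance is optional)
  res1 <- run_test(stream, "STEET", start_times = 0)
  expect_equal(res1$total_duration, res1$attempts$duration[1])

  # a single side bridge attempt is its own total
  flat <- tibble::tibble(t = seq(0, 120, by = 1 / fs), roll_deg = 0)
  sb <- run_test(flat, "SBET_LEFT", start_times = 0, stop_times = 84)
  expect_equal(sb$total_duration, 84, tolerance = 1 / fs)
  expect_equal(sb$category, "good")
})

test_that("run_test integrates EMG fatigue over the attempt windows", {
  stream <- tibble::tibble(t = seq(0, 100, by = 1 / 51.2), roll_deg = 0)
  emg <- simulate_emg(emg_scenario(baseline_rms = 0.2, seed = 4), duration = 100)
  res <- run_test(stream, "SBET_RIGHT", start_times = 0, stop_times = 60, emg_stream = emg)
  expect_false(is.null(res$fatigue))
  expect_equal(res$fatigue$rms, 0.2, tolerance = 0.05)
  g <- glance(res)
  expect_equal(g$rms, res$fatigue$rms)
  td <- tidy(res)
  expect_equal(td$protocol, "SBET_RIGHT")

  # without EMG the fatigue block is absent but scoring still works
  res2 <- run_test(stream, "SBET_RIGHT", start_times = 0, stop_times = 60)
  expect_null(res2$fatigue)
  expect_true(is.na(glance(res2)$rms))
})

test_that("no attempt exceeds 240 s and reasons are always populated", {
  set.seed(7)
  for (i in 1:20) {
    h <- stats::runif(1, 1, 300)
    sc <- posture_scenario(0, h, droop_rate = 15, tremor_sd = 0, seed = i)
    stream <- truth_angle_stream(sc)
    a <- run_attempt(stream, "STEET", 0)
    expect_lte(a$duration, 240)
    expect_true(a$termination_reason %in% c("angle_exceeded", "max_duration"))
  }
})
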