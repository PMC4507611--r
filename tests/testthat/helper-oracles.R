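# Independent oracles used across test files.

# Elementary rotation matrices (sensor -> earth), angle in degrees.
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}
# Z-Y-X (yaw-pitch-roll) composed rotation.
rot_zyx <- function(yaw, pitch, roll) rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)

# Closed-form quaternion for rotation at constant body rate omega (rad/s)
# over time tt, starting from the identity.
integrate_const_rate <- function(omega, tt) {
  n <- sqrt(sum(omega^2))
  if (n == 0) return(c(1, 0, 0, 0))
  half <- n * tt / 2
  c(cos(half), sin(half) * omega / n)
}

# One-way ANOVA mean squares via stats::aov (independent route).
aov_ms <- function(a, b) {
  d <- data.frame(
    y = c(a, b),
    subj = factor(rep(seq_along(a), 2))
  )
  tab <- summary(stats::aov(y ~ subj, data = d))[[1]]
  list(msb = tab["subj", "Mean Sq"], msw = tab["Residuals", "Mean Sq"])
}

# Ground-truth angle stream for a hold-then-droop posture (no filter).
truth_angle_stream <- function(scenario, duration = NULL, sample_rate = 51.2) {
  traj <- simulate_trajectory(scenario, sample_rate = sample_rate, duration = duration)
  traj[, c("t", "roll_deg")]
}

# Scratch directory cleaned up when the calling test finishes.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("trunkdx-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
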