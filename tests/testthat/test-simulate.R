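test_that("simulator parameters are validated", {
  expect_error(gait_sim_params(swing_fraction = 0.6),
               class = "gaitq_validation_error")
  expect_error(gait_sim_params(stride_length = 2.0, leg_length = 0.9),
               class = "gaitq_validation_error")
  expect_error(gait_sim_params(double_support_fraction = 0.35),
               class = "gaitq_validation_error")
  p <- gait_sim_params(swing_fraction = 0.4,
                       double_support_fraction = 0.2)
  expect_equal(p$double_support_fraction, 0.2)
  expect_error(gait_sim_params(packet_loss = 1),
               class = "gaitq_validation_error")
})

test_that("leg trajectories are antiphase with the configured period", {
  p <- gait_sim_params(cadence = 120)   # per-leg period 1.0 s
  expect_equal(p$stride_period, 1.0)
  t <- seq(0, 5, by = 1 / 59)
  ang <- joint_trajectories(t, p)
  # right leg lags the left by half a period (0.5 s at cadence 120)
  shifted <- joint_trajectories(t + 0.5, p)
  expect_equal(ang[, "shank_r"], shifted[, "shank_l"], tolerance = 1e-9,
               ignore_attr = TRUE)
  # one full period returns the waveform to itself
  expect_equal(joint_trajectories(t + 1.0, p), ang, tolerance = 1e-9)
})

test_that("arm swing can be disabled and the heel angle inverts the stride formula", {
  p0 <- gait_sim_params(arm_swing = 0)
  t <- seq(0, 3, by = 1 / 59)
  ang <- joint_trajectories(t, p0)
  expect_equal(ang[, "upper_arm_l"], rep(0, length(t)), ignore_attr = TRUE)
  expect_equal(ang[, "fore_arm_r"], rep(0, length(t)), ignore_attr = TRUE)
  p <- gait_sim_params(stride_length = 1.2, leg_length = 0.9)
  expect_equal(2 * p$leg_length * sin(p$heel_angle * pi / 180),
               p$stride_length, tolerance = 1e-6)
  # shank amplitude equals the heel-contact angle
  expect_equal(max(ang[, "shank_l"]), p0$heel_angle, tolerance = 0.05)
})

test_that("angles map to lateral-axis quaternions and back", {
  expect_equal(angles_to_quaternions(0)[1, ], c(w = 1, x = 0, y = 0, z = 0))
  q90 <- angles_to_quaternions(90)[1, ]
  expect_equal(unname(q90), c(cos(pi / 4), 0, 0, sin(pi / 4)), tolerance = 1e-12)
  thetas <- seq(-89, 89, by = 7)
  qm <- angles_to_quaternions(thetas)
  back <- vapply(seq_along(thetas), function(i) {
    sagittal_angle(quaternion(qm[i, 1], qm[i, 2], qm[i, 3], qm[i, 4]))
  }, numeric(1))
  expect_equal(back, thetas, tolerance = 1e-6)
})

test_that("identical seeds reproduce trials byte for byte", {
  p <- gait_sim_params(duration = 5, seed = 99)
  t1 <- simulate_trial(p)
  t2 <- simulate_trial(p)
  expect_identical(t1$recording, t2$recording)
  expect_identical(t1$truth[names(t1$truth) != "params"],
                   t2$truth[names(t2$truth) != "params"])
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_recording(t1$recording, f1)
  write_recording(t2$recording, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- simulate_trial(gait_sim_params(duration = 5, seed = 100))
  expect_false(identical(t1$recording$values, t3$recording$values))
})

test_that("a 10 s lossless trial yields 590 complete frames", {
  p <- gait_sim_params(duration = 10, packet_loss = 0, seed = 3)
  rec <- simulate_trial(p)$recording
  expect_equal(n_frames(rec), 590)
  expect_equal(ncol(rec$values), 40)
  expect_true(all(rec$mask))
})

test_that("ground-truth events match the closed form for a periodic clock", {
  p <- gait_sim_params(duration = 10, noise_sd = 0, packet_loss = 0,
                       phase_jitter = 0, seed = 3)
  tr <- simulate_trial(p)
  P <- p$stride_period
  phi0 <- p$initial_phase / (2 * pi)
  ks <- seq(-2, 12)
  cf <- P * (ks - phi0)
  cf <- cf[cf >= 0 & cf <= max(tr$recording$timestamps)]
  expect_equal(tr$truth$H_left, cf, tolerance = 1e-9)
  cf_t <- P * (ks + (1 - p$swing_fraction) - phi0)
  cf_t <- cf_t[cf_t >= 0 & cf_t <= max(tr$recording$timestamps)]
  expect_equal(tr$truth$T_left, cf_t, tolerance = 1e-9)
})

test_that("a deterministic trial is recovered within event quantization", {
  p <- gait_sim_params(duration = 30, noise_sd = 0, packet_loss = 0,
                       phase_jitter = 0, seed = 7)
  tr <- simulate_trial(p)
  ls <- angle_series(tr$recording, "left")
  rs <- angle_series(tr$recording, "right")
  ev <- extract_events(ls$angle, rs$angle, ls$time)
  tt <- tr$truth
  worst <- function(det, tru) max(vapply(det, function(d) min(abs(d - tru)),
                                         numeric(1)))
  tol <- 1 / 59 + 1e-9
  expect_lt(worst(ev$H_left, tt$H_left), tol)
  expect_lt(worst(ev$T_left, tt$T_left), tol)
  expect_lt(worst(ev$H_right, tt$H_right), tol)
  expect_lt(worst(ev$T_right, tt$T_right), tol)
  r <- gait_report(tr$recording, subject_params(p$leg_length, tt$distance))
  expect_equal(r$cadence_steps_min, tt$cadence, tolerance = 0.005)
  expect_equal(r$gait_speed_m_min, tt$gait_speed_m_min, tolerance = 0.005)
  expect_equal(r$stride_length_cm, tt$stride_length_cm, tolerance = 0.01)
  expect_lt(abs(r$swing_left - tt$swing_fraction), 0.03)
  # double support accumulates up to 2 samples of quantization per interval
  expect_lt(abs(r$double_support - tt$double_support), 0.05)
})

test_that("recovery error grows monotonically with sensor noise", {
  event_error <- function(noise, seed) {
    p <- gait_sim_params(duration = 20, noise_sd = noise, packet_loss = 0.02,
                         seed = seed)
    tr <- simulate_trial(p)
    ls <- angle_series(tr$recording, "left")
    rs <- angle_series(tr$recording, "right")
    ev <- extract_events(ls$angle, rs$angle, ls$time)
    tt <- tr$truth
    m <- function(det, tru) mean(vapply(det, function(d) min(abs(d - tru)),
                                        numeric(1)))
    mean(c(m(ev$H_left, tt$H_left), m(ev$T_left, tt$T_left),
           m(ev$H_right, tt$H_right), m(ev$T_right, tt$T_right)))
  }
  err <- vapply(c(0, 1, 3, 5), function(noise) {
    mean(vapply(1:10, function(s) event_error(noise, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})

test_that("ground truth sidecars round-trip through JSON", {
  tr <- simulate_trial(gait_sim_params(duration = 5, seed = 21))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(tr$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$H_left, tr$truth$H_left)
  expect_equal(back$cadence, tr$truth$cadence)
  expect_equal(back$swing_fraction, tr$truth$swing_fraction)
})
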