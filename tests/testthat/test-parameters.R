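test_that("double support matches hand substitution into its formula", {
  # H = [0, 1, 2], T = [0.2, 1.2, 2.2], Ttotal = 2.4:
  # only the first n-1 = 2 pairs enter: (0.2 + 0.2) / 2.4
  expect_equal(double_support_pairs(c(0, 1, 2), c(0.2, 1.2, 2.2), 2.4),
               0.4 / 2.4, tolerance = 1e-9)
  expect_equal(double_support_pairs(c(0, 1, 2), c(0, 1, 2), 2.4), 0)
  expect_error(double_support_pairs(c(0, 1), c(0.5, 0.9), 0),
               class = "gaitq_validation_error")
  expect_error(double_support_pairs(c(0, 1), c(-0.1, 1.2), 2),
               class = "gaitq_validation_error")
})

test_that("pooled double support pairs each heel contact with the opposite toe-off", {
  ev <- make_events(H_left = c(0, 1, 2), T_left = c(0.7, 1.7, 2.7),
                    H_right = c(0.5, 1.5, 2.5), T_right = c(0.2, 1.2, 2.2),
                    t_total = 3)
  # left contacts 0,1 pair with right toe-offs 0.2,1.2 (0.2 each);
  # right contacts 0.5,1.5 pair with left toe-offs 0.7,1.7 (0.2 each)
  expect_equal(double_support(ev), (0.2 * 4) / 3, tolerance = 1e-9)
  per_leg <- double_support(ev, by_leg = TRUE)
  expect_equal(unname(per_leg["left"] + per_leg["right"]),
               unname(per_leg["total"]), tolerance = 1e-12)
})

test_that("stride length applies l*sin(angle) per contact pair", {
  ev <- make_events(c(0, 1), numeric(0), c(0.5, 1.5), numeric(0), 2)
  expect_equal(as.numeric(stride_length(ev, 1.0,
                                        angles_left = c(30, 30),
                                        angles_right = c(30, 30))),
               100, tolerance = 1e-9)
  expect_equal(as.numeric(stride_length(ev, 1.0,
                                        angles_left = c(0, 0),
                                        angles_right = c(0, 0))),
               0, tolerance = 1e-12)
  # scale property: doubling leg length doubles stride length
  s1 <- as.numeric(stride_length(ev, 0.9, c(25, 35), c(28, 31)))
  s2 <- as.numeric(stride_length(ev, 1.8, c(25, 35), c(28, 31)))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_warning(stride_length(ev, 1.0, angles_left = c(95, 30),
                               angles_right = c(30, 30)),
                 "implausible")
})

test_that("gait speed converts distance over duration to metres per minute", {
  expect_equal(gait_speed(10, 12), 50)
  expect_equal(gait_speed(44, 60), 44)
  expect_equal(gait_speed(20, 12), 2 * gait_speed(10, 12))
  expect_error(gait_speed(0, 10), class = "gaitq_validation_error")
  expect_error(gait_speed(10, 0), class = "gaitq_validation_error")
})

test_that("cadence estimators agree with their closed forms", {
  # 10 heel contacts per leg over 15 s
  ev <- make_events(H_left = seq(0.25, 13.75, by = 1.5),
                    T_left = numeric(0),
                    H_right = seq(1.0, 14.5, by = 1.5),
                    T_right = numeric(0), t_total = 15)
  expect_equal(cadence(ev, mode = "count"), 20 * 60 / 15)   # 80 steps/min
  expect_equal(cadence(ev, mode = "strides"), 10 * 60 / 15) # 40 strides/min
  # interval-based rate on perfectly periodic steps is exact
  expect_equal(cadence(ev, mode = "rate"), 80, tolerance = 1e-9)
  ev0 <- make_events(numeric(0), numeric(0), numeric(0), numeric(0), 10)
  expect_warning(z <- cadence(ev0), "fewer than 2")
  expect_equal(z, 0)
})

test_that("detected cadence on a noiseless antiphase sinusoid equals 2/period", {
  t <- seq(0, 10 - 1e-9, by = 1 / 59)
  left <- 30 * sin(2 * pi * t / 1.5)
  ev <- extract_events(left, -left, t)
  expect_equal(cadence(ev, mode = "rate"), 2 / 1.5 * 60, tolerance = 1)
})

test_that("swing phase uses the same leg's toe-off within each cycle", {
  ev <- make_events(H_left = c(0, 1.0), T_left = 0.6,
                    H_right = c(0.5, 1.5), T_right = 1.1, t_total = 2)
  sw <- swing_phase(ev, "left")
  expect_equal(sw$seconds, 0.4, tolerance = 1e-12)
  expect_equal(sw$fraction, 0.4, tolerance = 1e-12)
  # toe-off at every cycle midpoint -> fraction 0.5
  ev2 <- make_events(H_left = 0:4, T_left = 0:3 + 0.5,
                     H_right = 0:4 + 0.5, T_right = 0:4 + 0.9, t_total = 5)
  expect_equal(swing_phase(ev2, "left")$fraction, 0.5, tolerance = 1e-12)
  # a cycle without a toe-off is skipped with a warning
  ev3 <- make_events(H_left = c(0, 1, 2), T_left = 0.6,
                     H_right = c(0.5, 1.5), T_right = c(0.2, 1.2), t_total = 2.5)
  expect_warning(sw3 <- swing_phase(ev3, "left"), "skipped")
  expect_equal(sw3$seconds, 0.4, tolerance = 1e-12)
})

test_that("time dilation rescales rates but not fractions", {
  H_l <- c(0.3, 1.8, 3.3); T_l <- c(1.2, 2.7)
  H_r <- c(1.05, 2.55, 4.05); T_r <- c(0.45, 1.95, 3.45)
  k <- 3
  ev <- make_events(H_l, T_l, H_r, T_r, t_total = 4.5)
  evk <- make_events(k * H_l, k * T_l, k * H_r, k * T_r, t_total = k * 4.5)
  expect_equal(cadence(evk), cadence(ev) / k, tolerance = 1e-12)
  expect_equal(gait_speed(10, evk$t_total), gait_speed(10, ev$t_total) / k,
               tolerance = 1e-12)
  expect_equal(double_support(evk), double_support(ev), tolerance = 1e-12)
  expect_equal(swing_phase(evk, "left")$fraction,
               swing_phase(ev, "left")$fraction, tolerance = 1e-12)
})

test_that("timing-based parameters ignore constant angle-calibration offsets", {
  t <- seq(0, 12 - 1e-9, by = 1 / 59)
  left <- 28 * sin(2 * pi * t / 1.4)
  right <- 28 * sin(2 * pi * (t / 1.4 - 0.5))
  ev0 <- extract_events(left, right, t)
  ev1 <- extract_events(left + 17, right + 17, t)
  expect_equal(ev1$H_left, ev0$H_left, tolerance = 1e-6)
  expect_equal(cadence(ev1), cadence(ev0), tolerance = 1e-6)
  expect_equal(double_support(ev1), double_support(ev0), tolerance = 1e-6)
  expect_equal(swing_phase(ev1, "right")$fraction,
               swing_phase(ev0, "right")$fraction, tolerance = 1e-6)
})

test_that("the full report is deterministic and propagates insufficient cycles", {
  p <- gait_sim_params(duration = 12, seed = 5)
  tr <- simulate_trial(p)
  subj <- subject_params(p$leg_length, tr$truth$distance)
  r1 <- gait_report(tr$recording, subj)
  r2 <- gait_report(tr$recording, subj)
  expect_identical(r1[names(r1) != "events"], r2[names(r2) != "events"])
  expect_true(all(c(r1$stride_length_cm, r1$gait_speed_m_min,
                    r1$cadence_steps_min) > 0))
  expect_true(r1$double_support >= 0 && r1$double_support <= 1)
  expect_true(r1$swing_left >= 0 && r1$swing_left <= 1)
  short <- simulate_trial(gait_sim_params(duration = 1.2, seed = 5))
  expect_error(gait_report(short$recording, subj),
               class = "gaitq_insufficient_cycles")
})

test_that("report serialisation carries values and units", {
  p <- gait_sim_params(duration = 12, seed = 6)
  tr <- simulate_trial(p)
  rep <- gait_report(tr$recording, subject_params(0.9, tr$truth$distance))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_gait_report(rep, jf, "json")
  write_gait_report(rep, tf, "text")
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(parsed$stride_length$value, rep$stride_length_cm)
  expect_equal(parsed$cadence$unit, "steps/min")
  expect_true(any(grepl("^double_support=", readLines(tf))))
})
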