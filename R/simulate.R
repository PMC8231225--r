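#' Parameters for the synthetic walking-trial simulator
#'
#' The simulator replaces the wearable hardware: it generates a ten-sensor
#' quaternion packet stream for a subject walking with prescribed
#' spatiotemporal parameters, then degrades it with sensor noise and
#' random packet loss, so that every analysis stage can be validated
#' against analytic ground truth.
#'
#' The gait-cycle identity `double support = 1 - 2 * swing` ties the two
#' phase fractions together (each leg's single-support time equals the
#' other leg's swing time); `double_support_fraction` may be supplied but
#' must be consistent with `swing_fraction`.
#'
#' @param cadence steps per minute (default 80, a typical self-selected
#'   walking rate).
#' @param stride_length stride length in metres (default 1.2).
#' @param leg_length leg length in metres (default 0.9); with the default
#'   stride this gives a heel-contact shank angle of about 42 degrees.
#' @param swing_fraction swing phase as a fraction of the gait cycle, in
#'   (0, 0.5) (default 0.4).
#' @param double_support_fraction optional; must equal
#'   `1 - 2 * swing_fraction` (default, derived).
#' @param duration trial duration in seconds (default 10).
#' @param rate sampling rate in Hz (default 59).
#' @param noise_sd Gaussian angle noise, degrees (default 1).
#' @param packet_loss i.i.d. per-packet drop probability (default 0.02).
#' @param arm_swing arm-swing amplitude in degrees (default 15); arms move
#'   in antiphase to the ipsilateral leg when `phase_lock` is on.
#' @param phase_lock logical: lock arm phases to the legs (default `TRUE`);
#'   when off, each arm gets an independent random phase.
#' @param phase_jitter cycle-to-cycle timing variability, the standard
#'   deviation of a random walk on the gait phase in radians per sqrt
#'   second (default 0.15, about 3% stride-time variability, typical of
#'   healthy gait). All segments of a trial share the jittered gait clock,
#'   so interlimb phase locking is preserved; 0 gives strictly periodic
#'   gait.
#' @param initial_phase left-leg phase (radians) at trial start (default
#'   `pi / 3`, so the first events fall inside the trial).
#' @param seed integer seed fixing all randomness.
#' @return Object of class `"gait_sim_params"`.
#' @export
gait_sim_params <- function(cadence = 80, stride_length = 1.2,
                            leg_length = 0.9, swing_fraction = 0.4,
                            double_support_fraction = NULL, duration = 10,
                            rate = 59, noise_sd = 1, packet_loss = 0.02,
                            arm_swing = 15, phase_lock = TRUE,
                            phase_jitter = 0.15,
                            initial_phase = pi / 3, seed = 1L) {
  chk <- function(ok, msg, ...) if (!ok) stop_validation(msg, ...)
  chk(is.numeric(cadence) && cadence > 0, "cadence must be > 0")
  chk(is.numeric(stride_length) && stride_length > 0, "stride_length must be > 0")
  chk(is.numeric(leg_length) && leg_length > 0, "leg_length must be > 0")
  chk(stride_length < 2 * leg_length,
      "stride_length must be below 2 * leg_length (heel-contact angle < 90 deg)")
  chk(is.numeric(swing_fraction) && swing_fraction > 0 && swing_fraction < 0.5,
      "swing_fraction must lie in (0, 0.5)")
  ds <- 1 - 2 * swing_fraction
  if (!is.null(double_support_fraction) &&
      abs(double_support_fraction - ds) > 1e-9) {
    stop_validation(
      "double_support_fraction (%.3f) is inconsistent with swing_fraction: the gait cycle requires 1 - 2*swing = %.3f",
      double_support_fraction, ds)
  }
  chk(is.numeric(duration) && duration > 0, "duration must be > 0")
  chk(is.numeric(rate) && rate > 0, "rate must be > 0")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  chk(is.numeric(packet_loss) && packet_loss >= 0 && packet_loss < 1,
      "packet_loss must lie in [0, 1)")
  chk(is.numeric(arm_swing) && arm_swing >= 0, "arm_swing must be >= 0")
  chk(is.numeric(phase_jitter) && phase_jitter >= 0, "phase_jitter must be >= 0")
  structure(list(
    cadence = cadence, stride_length = stride_length, leg_length = leg_length,
    swing_fraction = swing_fraction, double_support_fraction = ds,
    duration = duration, rate = rate, noise_sd = noise_sd,
    packet_loss = packet_loss, arm_swing = arm_swing,
    phase_lock = isTRUE(phase_lock), phase_jitter = phase_jitter,
    initial_phase = initial_phase,
    seed = as.integer(seed),
    stride_period = 120 / cadence,
    heel_angle = asin(stride_length / (2 * leg_length)) * 180 / pi
  ), class = "gait_sim_params")
}

#' @export
print.gait_sim_params <- function(x, ...) {
  cat(sprintf(
    "<gait_sim_params> cadence %.0f steps/min, stride %.2f m, %g s at %g Hz\n",
    x$cadence, x$stride_length, x$duration, x$rate))
  cat(sprintf("  swing %.2f / double support %.2f; noise %.1f deg, loss %.1f%%, seed %d\n",
              x$swing_fraction, x$double_support_fraction, x$noise_sd,
              100 * x$packet_loss, x$seed))
  invisible(x)
}

# Phase-warped cosine: a piecewise-linear bijection of the cycle phase maps
# the maximum to phase 0 and the minimum to 2*pi*(1 - swing), so heel
# contact (max) and toe-off (min) land at the configured points of the
# cycle while keeping closed-form event times.
warp_phase <- function(phi, swing) {
  phi <- phi %% (2 * pi)
  pm <- 2 * pi * (1 - swing)
  ifelse(phi <= pm, phi * pi / pm, pi + (phi - pm) * pi / (2 * pi - pm))
}

# relative sagittal amplitude of each segment (shank carries the full
# heel-contact amplitude; thigh and foot scaled versions of the same cycle)
seg_amp_ratio <- c(thigh = 0.6, shank = 1.0, foot = 0.8)

#' Ground-truth sagittal angle trajectories for all ten segments
#'
#' The kinematic model: each leg segment follows a phase-warped cosine of
#' the leg's gait phase, legs in antiphase, with the shank amplitude set so
#' that the heel-contact angle reproduces the configured stride length
#' through `2 * l * sin(angle) = stride`. Arms swing in antiphase to the
#' ipsilateral leg (when phase-locked). The model is chosen for analytic
#' event times, not biomechanical fidelity.
#'
#' @param t numeric vector of times in seconds.
#' @param params a [gait_sim_params()].
#' @param arm_offsets optional numeric length-2 vector of extra phase
#'   offsets (radians) for the left and right arm (used when
#'   `phase_lock = FALSE`).
#' @return Matrix `length(t)` x 10 of sagittal angles in degrees, columns
#'   named by segment.
#' @export
joint_trajectories <- function(t, params, arm_offsets = c(0, 0)) {
  stopifnot(inherits(params, "gait_sim_params"))
  phi_l <- 2 * pi * t / params$stride_period + params$initial_phase
  trajectories_from_phase(phi_l, params, arm_offsets)
}

# Trajectories as a function of the (possibly jittered) left-leg gait
# phase; every segment of the trial reads the same gait clock.
trajectories_from_phase <- function(phi_l, params, arm_offsets = c(0, 0)) {
  s <- params$swing_fraction
  A <- params$heel_angle
  phi_r <- phi_l + pi
  base_l <- cos(warp_phase(phi_l, s))
  base_r <- cos(warp_phase(phi_r, s))
  arm_l <- cos(warp_phase(phi_l + pi + arm_offsets[1], s))
  arm_r <- cos(warp_phase(phi_r + pi + arm_offsets[2], s))
  out <- cbind(
    upper_arm_l = params$arm_swing * arm_l,
    fore_arm_l = 0.8 * params$arm_swing * arm_l,
    upper_arm_r = params$arm_swing * arm_r,
    fore_arm_r = 0.8 * params$arm_swing * arm_r,
    thigh_l = seg_amp_ratio[["thigh"]] * A * base_l,
    shank_l = seg_amp_ratio[["shank"]] * A * base_l,
    foot_l = seg_amp_ratio[["foot"]] * A * base_l,
    thigh_r = seg_amp_ratio[["thigh"]] * A * base_r,
    shank_r = seg_amp_ratio[["shank"]] * A * base_r,
    foot_r = seg_amp_ratio[["foot"]] * A * base_r
  )
  out
}

#' Convert sagittal angles to sensor quaternions
#'
#' Each sagittal angle becomes a rotation about the lateral (z) axis, the
#' axis of flexion/extension; an angle of zero maps to the identity
#' quaternion (the sensor's rest/calibration pose).
#'
#' @param angles numeric vector or matrix of sagittal angles in degrees.
#' @return For a vector, an n x 4 matrix of `(w, x, y, z)` components; for
#'   a matrix, an n x (4 * ncol) matrix with four columns per input column.
#' @export
angles_to_quaternions <- function(angles) {
  if (is.matrix(angles)) {
    out <- matrix(NA_real_, nrow(angles), 4L * ncol(angles))
    for (j in seq_len(ncol(angles))) {
      out[, 4L * (j - 1L) + 1:4] <- angles_to_quaternions(angles[, j])
    }
    return(out)
  }
  half <- angles * pi / 360
  cbind(w = cos(half), x = 0, y = 0, z = sin(half))
}

# Times at which the phase path crosses cycle fraction `frac` (upward),
# by linear interpolation between samples; exact for a strictly periodic
# (linear) phase.
phase_crossings <- function(t, phi, frac) {
  n <- length(phi)
  lo <- floor(phi[1] / (2 * pi) - frac) - 1
  hi <- ceiling(phi[n] / (2 * pi) - frac) + 1
  out <- numeric(0)
  for (k in lo:hi) {
    v <- 2 * pi * (k + frac)
    i <- which(phi[-n] <= v & phi[-1] > v)
    if (length(i) >= 1) {
      i <- i[1]
      out <- c(out, t[i] + (v - phi[i]) / (phi[i + 1] - phi[i]) *
                 (t[i + 1] - t[i]))
    }
  }
  sort(out)
}

ground_truth_events <- function(t, phi_l, swing) {
  list(
    H_left = phase_crossings(t, phi_l, 0),
    T_left = phase_crossings(t, phi_l, 1 - swing),
    H_right = phase_crossings(t, phi_l, 0.5),
    T_right = phase_crossings(t, phi_l, (1 - swing + 0.5) %% 1)
  )
}

#' Simulate a complete ten-sensor walking trial
#'
#' Samples the ground-truth trajectories on the frame grid, adds seeded
#' Gaussian angle noise, converts to quaternions, emits one packet per
#' sensor per frame, applies seeded i.i.d. packet loss, and assembles the
#' surviving packets into a recording. Identical parameters (including the
#' seed) give byte-identical output.
#'
#' @param params a [gait_sim_params()].
#' @return List with `recording` (a [gait_recording()]) and `truth` (class
#'   `"gait_ground_truth"`): analytic event times per leg, the five true
#'   gait parameters, the walked distance, and per-segment phase offsets.
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "gait_sim_params"))
  with_seed(params$seed, {
    n <- round(params$duration * params$rate)
    t <- (0:(n - 1L)) / params$rate
    arm_off <- if (params$phase_lock) c(0, 0) else stats::runif(2, 0, 2 * pi)
    phi_l <- 2 * pi * t / params$stride_period + params$initial_phase
    if (params$phase_jitter > 0) {
      dt <- 1 / params$rate
      phi_l <- phi_l + cumsum(c(0, stats::rnorm(n - 1L, 0,
                                                params$phase_jitter * sqrt(dt))))
    }
    ang <- trajectories_from_phase(phi_l, params, arm_off)
    if (params$noise_sd > 0) {
      ang <- ang + matrix(stats::rnorm(length(ang), 0, params$noise_sd),
                          nrow(ang))
    }
    qm <- angles_to_quaternions(ang)  # columns follow segment order
    # segment column block -> sensor ID via the default map
    map <- default_sensor_map()
    segs <- colnames(joint_trajectories(0, params))
    packets <- data.frame(
      timestamp = rep(t, times = 10),
      sensor_id = rep(unname(map[segs]), each = n),
      w = as.numeric(qm[, 4 * (seq_along(segs) - 1) + 1]),
      x = as.numeric(qm[, 4 * (seq_along(segs) - 1) + 2]),
      y = as.numeric(qm[, 4 * (seq_along(segs) - 1) + 3]),
      z = as.numeric(qm[, 4 * (seq_along(segs) - 1) + 4])
    )
    if (params$packet_loss > 0) {
      packets <- packets[stats::runif(nrow(packets)) >= params$packet_loss, ,
                         drop = FALSE]
    }
    rec <- assemble_frames(packets, params$rate, subject = "simulated",
                           trial = sprintf("seed%d", params$seed))
    evt <- ground_truth_events(t, phi_l, params$swing_fraction)
    # realised (not nominal) rate and distance: the jittered gait clock of
    # this trial is the truth the analysis should recover
    span <- t[n] - t[1]
    dphi <- phi_l[n] - phi_l[1]
    truth <- structure(list(
      H_left = evt$H_left, T_left = evt$T_left,
      H_right = evt$H_right, T_right = evt$T_right,
      cadence = 60 * dphi / (pi * span),
      stride_length_cm = params$stride_length * 100,
      gait_speed_m_min = params$stride_length * dphi / (2 * pi) / span * 60,
      double_support = params$double_support_fraction,
      swing_fraction = params$swing_fraction,
      distance = params$stride_length * dphi / (2 * pi),
      heel_angle = params$heel_angle,
      phase_offsets = c(leg_left = 0, leg_right = pi,
                        arm_left = pi + arm_off[1], arm_right = pi + arm_off[2]),
      params = params
    ), class = "gait_ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<gait_ground_truth> cadence %.0f, stride %.0f cm, speed %.1f m/min, DS %.2f, swing %.2f\n",
    x$cadence, x$stride_length_cm, x$gait_speed_m_min, x$double_support,
    x$swing_fraction))
  cat(sprintf("  %d+%d heel contacts, distance %.1f m\n",
              length(x$H_left), length(x$H_right), x$distance))
  invisible(x)
}

#' Write simulator ground truth as a JSON sidecar file
#'
#' @param truth a ground-truth object from [simulate_trial()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "gait_ground_truth"))
  out <- truth[c("H_left", "T_left", "H_right", "T_right", "cadence",
                 "stride_length_cm", "gait_speed_m_min", "double_support",
                 "swing_fraction", "distance", "heel_angle")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar file
#' @param path path written by [write_ground_truth()].
#' @return List of ground-truth fields.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop_format("ground-truth file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
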