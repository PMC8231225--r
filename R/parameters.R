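#' Subject parameters for gait analysis
#'
#' @param leg_length leg length `l` in metres (used by the stride-length
#'   formula).
#' @param distance walked distance `d` in metres (used by gait speed).
#' @return Object of class `"subject_params"`.
#' @export
subject_params <- function(leg_length, distance) {
  if (!is.numeric(leg_length) || length(leg_length) != 1 || is.na(leg_length) ||
      leg_length <= 0) {
    stop_validation("leg_length must be a positive number (metres)")
  }
  if (!is.numeric(distance) || length(distance) != 1 || is.na(distance) ||
      distance <= 0) {
    stop_validation("distance must be a positive number (metres)")
  }
  structure(list(leg_length = leg_length, distance = distance),
            class = "subject_params")
}

#' Double-support fraction from paired event vectors
#'
#' The literal double-support formula: with `H` the heel-contact times and
#' `T` the paired opposite-leg toe-off times,
#' `sum_{i=1}^{n-1} (T(i) - H(i)) / t_total`, where `n` is the number of
#' heel contacts. Only the first `n - 1` pairs enter the sum.
#'
#' @param H,T numeric vectors of equal length: heel-contact times and the
#'   opposite-leg toe-off times paired to them (seconds).
#' @param t_total trial duration in seconds, `> 0`.
#' @return Double-support fraction of the trial.
#' @export
double_support_pairs <- function(H, T, t_total) {
  if (length(H) != length(T)) stop_validation("H and T must have equal length")
  if (length(H) < 2L) {
    stop_insufficient_cycles("double support needs at least 2 paired events")
  }
  if (!is.numeric(t_total) || t_total <= 0) {
    stop_validation("t_total must be > 0")
  }
  d <- T - H
  if (any(d < 0)) {
    stop_validation("event pairing error: a toe-off precedes its heel contact")
  }
  n <- length(H)
  sum(d[seq_len(n - 1L)]) / t_total
}

# For each heel contact of one leg (dropping the last, which has no
# following cycle), the first strictly later toe-off of the OPPOSITE leg.
pair_opposite_toeoff <- function(H, T_opp) {
  n <- length(H)
  if (n < 2L) return(list(H = numeric(0), T = numeric(0)))
  h <- H[seq_len(n - 1L)]
  t <- vapply(h, function(hc) {
    later <- T_opp[T_opp > hc]
    if (length(later) == 0) NA_real_ else later[1]
  }, numeric(1))
  keep <- !is.na(t)
  list(H = h[keep], T = t[keep])
}

#' Double-support fraction of a trial
#'
#' Each heel contact starts a double-support interval that ends at the
#' opposite leg's next toe-off; the intervals from both legs' pairings are
#' pooled and their total duration divided by the trial duration.
#'
#' @param ev a [gait_events] object.
#' @param by_leg if `TRUE`, also return the per-leg contributions.
#' @return Double-support fraction in `[0, 1]` (named vector with `left`,
#'   `right` components when `by_leg = TRUE`).
#' @export
double_support <- function(ev, by_leg = FALSE) {
  stopifnot(inherits(ev, "gait_events"))
  pl <- pair_opposite_toeoff(ev$H_left, ev$T_right)
  pr <- pair_opposite_toeoff(ev$H_right, ev$T_left)
  if (length(pl$H) + length(pr$H) < 1L) {
    stop_insufficient_cycles("no heel-contact / opposite-toe-off pairs found")
  }
  dl <- pl$T - pl$H
  dr <- pr$T - pr$H
  if (any(c(dl, dr) < 0)) {
    stop_validation("event pairing error: a toe-off precedes its heel contact")
  }
  total <- sum(dl, dr) / ev$t_total
  if (by_leg) {
    c(total = total, left = sum(dl) / ev$t_total, right = sum(dr) / ev$t_total)
  } else {
    total
  }
}

#' Mean stride length from heel-contact angles
#'
#' Per gait cycle the stride length is
#' `l * sin(theta(i+1)) + l * sin(theta(i))`, with `theta(i)` the sagittal
#' segment angle at heel contact `i` and `l` the subject's leg length; the
#' mean over all cycles of both legs is reported in centimetres.
#'
#' @param ev a [gait_events] object.
#' @param leg_length leg length `l` in metres.
#' @param angles_left,angles_right sagittal angles (degrees) at each heel
#'   contact of the corresponding leg; by default the locally fitted
#'   heel-contact angles stored in `ev`.
#' @return Mean stride length in cm, with attribute `per_cycle` holding the
#'   individual cycle values. Angles of 90 degrees or more trigger an
#'   implausible-angle warning.
#' @export
stride_length <- function(ev, leg_length,
                          angles_left = ev$angle_H_left %||%
                            ev$series_left[ev$idx_H_left],
                          angles_right = ev$angle_H_right %||%
                            ev$series_right[ev$idx_H_right]) {
  stopifnot(inherits(ev, "gait_events"))
  if (!is.numeric(leg_length) || leg_length <= 0) {
    stop_validation("leg_length must be > 0")
  }
  per_leg <- function(th) {
    if (length(th) < 2L) return(numeric(0))
    if (any(abs(th) >= 90)) {
      warning("implausible heel-contact angle (|angle| >= 90 degrees)",
              call. = FALSE)
    }
    s <- sin(th * pi / 180) * leg_length
    s[-1] + s[-length(s)]
  }
  cycles <- c(per_leg(angles_left), per_leg(angles_right))
  if (length(cycles) == 0L) {
    stop_insufficient_cycles("stride length needs at least 2 heel contacts on a leg")
  }
  structure(mean(cycles) * 100, per_cycle = cycles * 100)
}

#' Gait speed
#'
#' @param distance walked distance `d` in metres.
#' @param t_total trial duration in seconds.
#' @return Speed in metres per minute, `d / t_total * 60`.
#' @export
gait_speed <- function(distance, t_total) {
  if (!is.numeric(distance) || distance <= 0) {
    stop_validation("distance must be > 0")
  }
  if (!is.numeric(t_total) || t_total <= 0) {
    stop_validation("t_total must be > 0")
  }
  distance / t_total * 60
}

#' Cadence in steps per minute
#'
#' Every heel contact counts as one step. Three estimators are offered:
#' `"rate"` (default) estimates the stepping rate from the pooled
#' heel-contact intervals, `(n_steps - 1) * 60 / (last - first contact)`,
#' which is unbiased on periodic gait regardless of where the trial window
#' cuts the cycle; `"count"` divides the raw step count by the trial
#' duration, `(n_left + n_right) * 60 / t_total`; `"strides"` is the
#' stride-count convention (number of peaks divided by two), reported as
#' strides per minute.
#'
#' @param ev a [gait_events] object.
#' @param mode `"rate"`, `"count"` or `"strides"`.
#' @return Cadence in steps (or strides) per minute; 0 with a warning when
#'   fewer than 2 heel contacts are present.
#' @export
cadence <- function(ev, mode = c("rate", "count", "strides")) {
  stopifnot(inherits(ev, "gait_events"))
  mode <- match.arg(mode)
  h <- sort(c(ev$H_left, ev$H_right))
  if (length(h) < 2L) {
    warning("fewer than 2 heel contacts; cadence reported as 0", call. = FALSE)
    return(0)
  }
  switch(mode,
    rate = (length(h) - 1L) * 60 / (h[length(h)] - h[1]),
    count = length(h) * 60 / ev$t_total,
    strides = (length(h) / 2) * 60 / ev$t_total
  )
}

#' Swing phase of one leg
#'
#' For each gait cycle `i` (between successive heel contacts `H(i)` and
#' `H(i+1)` of the same leg) the swing duration is `H(i+1) - T(i)` with
#' `T(i)` the same leg's toe-off inside the cycle; the fraction is that
#' duration divided by the cycle duration `H(i+1) - H(i)`. Cycles without a
#' toe-off are skipped with a warning.
#'
#' @param ev a [gait_events] object.
#' @param leg `"left"` or `"right"`.
#' @return List with `fraction` (mean swing fraction of the gait cycle),
#'   `seconds` (mean raw swing duration) and `per_cycle` (data frame of the
#'   cycle-level values).
#' @export
swing_phase <- function(ev, leg = c("left", "right")) {
  stopifnot(inherits(ev, "gait_events"))
  leg <- match.arg(leg)
  H <- if (leg == "left") ev$H_left else ev$H_right
  T_same <- if (leg == "left") ev$T_left else ev$T_right
  if (length(H) < 2L) {
    stop_insufficient_cycles("swing phase needs at least 2 heel contacts")
  }
  raw <- frac <- numeric(0)
  skipped <- 0L
  for (i in seq_len(length(H) - 1L)) {
    toff <- T_same[T_same > H[i] & T_same < H[i + 1L]]
    if (length(toff) == 0L) { skipped <- skipped + 1L; next }
    r <- H[i + 1L] - toff[1]
    raw <- c(raw, r)
    frac <- c(frac, r / (H[i + 1L] - H[i]))
  }
  if (skipped > 0L) {
    warning(sprintf("%d gait cycle(s) without a toe-off were skipped", skipped),
            call. = FALSE)
  }
  if (length(raw) == 0L) {
    stop_insufficient_cycles("no gait cycle contained a toe-off")
  }
  list(fraction = mean(frac), seconds = mean(raw),
       per_cycle = data.frame(swing_s = raw, fraction = frac))
}

#' Full five-parameter gait report for a recording
#'
#' Runs the whole analysis pipeline: per-leg angle series, event
#' extraction, and the five spatiotemporal parameters (stride length, gait
#' speed, cadence, double support, swing phase left/right). Deterministic
#' for a fixed recording and configuration.
#'
#' @param rec a [gait_recording()].
#' @param subject a [subject_params()] (leg length, walked distance).
#' @param mode angle signal used for event detection: `"shank_sagittal"`
#'   (default) or `"knee_flexion"`.
#' @param cadence_mode see [cadence()].
#' @param cfg a [skeleton_config()].
#' @param min_separation,min_prominence,smooth_window detector settings,
#'   see [extract_events()].
#' @return Object of class `"gait_report"` with the five parameters, their
#'   units, and the underlying [gait_events].
#' @export
gait_report <- function(rec, subject, mode = c("shank_sagittal", "knee_flexion"),
                        cadence_mode = c("rate", "count", "strides"),
                        cfg = skeleton_config(), min_separation = 0.4,
                        min_prominence = 5, smooth_window = 0.15) {
  stopifnot(inherits(rec, "gait_recording"), inherits(subject, "subject_params"))
  mode <- match.arg(mode)
  cadence_mode <- match.arg(cadence_mode)
  left <- angle_series(rec, "left", mode, cfg)
  right <- angle_series(rec, "right", mode, cfg)
  ev <- extract_events(left$angle, right$angle, left$time,
                       min_separation, min_prominence, smooth_window)
  sw_l <- swing_phase(ev, "left")
  sw_r <- swing_phase(ev, "right")
  structure(list(
    stride_length_cm = as.numeric(stride_length(ev, subject$leg_length)),
    gait_speed_m_min = gait_speed(subject$distance, ev$t_total),
    cadence_steps_min = cadence(ev, cadence_mode),
    double_support = double_support(ev),
    swing_left = sw_l$fraction,
    swing_right = sw_r$fraction,
    swing_left_s = sw_l$seconds,
    swing_right_s = sw_r$seconds,
    mode = mode, cadence_mode = cadence_mode,
    n_left = ev$n_left, n_right = ev$n_right, t_total = ev$t_total,
    subject = subject, events = ev
  ), class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  cat(sprintf("  Stride length   %7.1f cm\n", x$stride_length_cm))
  cat(sprintf("  Gait speed      %7.1f m/min\n", x$gait_speed_m_min))
  cat(sprintf("  Cadence         %7.1f steps/min (%s)\n",
              x$cadence_steps_min, x$cadence_mode))
  cat(sprintf("  Double support  %7.3f of trial\n", x$double_support))
  cat(sprintf("  Swing phase L   %7.3f of cycle (%.2f s)\n",
              x$swing_left, x$swing_left_s))
  cat(sprintf("  Swing phase R   %7.3f of cycle (%.2f s)\n",
              x$swing_right, x$swing_right_s))
  cat(sprintf("  [%d+%d heel contacts over %.1f s; %s signal]\n",
              x$n_left, x$n_right, x$t_total, x$mode))
  invisible(x)
}

#' Serialise a gait report
#'
#' @param report a [gait_report()].
#' @param path output file path.
#' @param format `"json"` (structured, with units) or `"text"` (key/value
#'   lines).
#' @return Invisibly, `path`.
#' @export
write_gait_report <- function(report, path, format = c("json", "text")) {
  stopifnot(inherits(report, "gait_report"))
  format <- match.arg(format)
  fields <- list(
    stride_length = list(value = report$stride_length_cm, unit = "cm"),
    gait_speed = list(value = report$gait_speed_m_min, unit = "m/min"),
    cadence = list(value = report$cadence_steps_min, unit = "steps/min"),
    double_support = list(value = report$double_support, unit = "fraction of trial"),
    swing_phase_left = list(value = report$swing_left, unit = "fraction of cycle"),
    swing_phase_right = list(value = report$swing_right, unit = "fraction of cycle"),
    swing_phase_left_s = list(value = report$swing_left_s, unit = "s"),
    swing_phase_right_s = list(value = report$swing_right_s, unit = "s")
  )
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(vapply(names(fields), function(k) {
      sprintf("%s=%.6f %s", k, fields[[k]]$value, fields[[k]]$unit)
    }, character(1)), path)
  }
  invisible(path)
}
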