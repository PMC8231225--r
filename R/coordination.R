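#' Lag-maximised normalised cross-correlation of two angle waveforms
#'
#' Both series are linearly detrended and mean-removed; the coefficient is
#' the maximum over integer-sample lags `|tau| <= max_lag` of the Pearson
#' correlation between `a(t)` and `b(t + tau)`. Lag-maximisation makes the
#' measure robust to phase offsets between limbs; set `max_lag = 0` for
#' plain zero-lag correlation.
#'
#' @param a,b numeric angle series sampled at the same rate (`NA` gaps are
#'   linearly interpolated); unequal lengths are truncated to the common
#'   length.
#' @param rate sampling rate in Hz.
#' @param max_lag maximum lag magnitude in seconds.
#' @return List with `coefficient` (in `[-1, 1]`) and `lag` (seconds, the
#'   lag attaining it). A zero-variance series raises an
#'   undefined-coefficient error.
#' @export
xcorr_max <- function(a, b, rate, max_lag = 1) {
  n <- min(length(a), length(b))
  if (n < 4L) stop_validation("series too short for cross-correlation")
  a <- prepare_series(as.numeric(a)[seq_len(n)], seq_len(n) / rate)
  b <- prepare_series(as.numeric(b)[seq_len(n)], seq_len(n) / rate)
  detrend <- function(x) {
    t <- seq_along(x)
    stats::residuals(stats::lm.fit(cbind(1, t), x))
  }
  a <- detrend(a)
  b <- detrend(b)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    stop_validation("zero-variance series: cross-correlation undefined",
                    extra_class = "gaitq_undefined_coefficient")
  }
  L <- as.integer(round(max_lag * rate))
  if (2L * L >= n) {
    stop_validation("series must be longer than twice the maximum lag")
  }
  best <- -Inf
  best_lag <- 0L
  for (lag in (-L):L) {
    if (lag >= 0) {
      r <- stats::cor(a[seq_len(n - lag)], b[seq_len(n - lag) + lag])
    } else {
      r <- stats::cor(a[seq_len(n + lag) - lag], b[seq_len(n + lag)])
    }
    if (!is.na(r) && r > best) {
      best <- r
      best_lag <- lag
    }
  }
  list(coefficient = best, lag = best_lag / rate)
}

coordination_series <- function(rec, segments, cfg) {
  map <- cfg$sensor_map
  missing <- setdiff(segments, names(map))
  if (length(missing) > 0) {
    stop_validation("unknown segment(s): %s", paste(missing, collapse = ", "))
  }
  out <- lapply(segments, function(seg) {
    id <- map[[seg]]
    m <- rec$values[, 4 * id + 1:4, drop = FALSE]
    m[!rec$mask[, id + 1L], ] <- NA_real_
    ang <- sagittal_angle_mat(m)
    if (all(is.na(ang))) {
      stop_validation("segment %s has no data in this trial", seg)
    }
    ang
  })
  names(out) <- segments
  out
}

#' Pairwise interlimb coordination matrix for one trial
#'
#' Computes the lag-maximised cross-correlation coefficient between the
#' sagittal angle waveforms of every unordered pair of the requested
#' segments.
#'
#' @param rec a [gait_recording()].
#' @param segments character vector of segment names (default: all ten).
#' @param max_lag maximum lag in seconds (default 1.5, about one gait
#'   cycle).
#' @param cfg a [skeleton_config()].
#' @return Object of class `"coordination_matrix"`: symmetric coefficient
#'   matrix (unit diagonal), matching lag matrix, and a long-format pair
#'   table.
#' @export
coordination_matrix <- function(rec, segments = names(default_sensor_map()),
                                max_lag = 1.5, cfg = skeleton_config()) {
  stopifnot(inherits(rec, "gait_recording"))
  ser <- coordination_series(rec, segments, cfg)
  k <- length(segments)
  co <- diag(1, k)
  lg <- matrix(0, k, k)
  dimnames(co) <- dimnames(lg) <- list(segments, segments)
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- xcorr_max(ser[[i]], ser[[j]], rec$rate, max_lag)
      co[i, j] <- co[j, i] <- r$coefficient
      lg[i, j] <- r$lag
      lg[j, i] <- -r$lag
      pairs[[length(pairs) + 1L]] <- data.frame(
        segment_a = segments[i], segment_b = segments[j],
        coefficient = r$coefficient, lag_s = r$lag)
    }
  }
  structure(list(coefficients = co, lags = lg,
                 pairs = do.call(rbind, pairs), segments = segments,
                 max_lag = max_lag),
            class = "coordination_matrix")
}

#' @export
print.coordination_matrix <- function(x, ...) {
  cat(sprintf("<coordination_matrix> %d segments, %d pairs\n",
              length(x$segments), nrow(x$pairs)))
  cat(sprintf("  coefficient median %.3f [%.3f, %.3f]\n",
              stats::median(x$pairs$coefficient),
              min(x$pairs$coefficient), max(x$pairs$coefficient)))
  invisible(x)
}

#' Same-trial versus cross-trial coordination comparison
#'
#' Interlimb coordination shows up as high cross-correlation between angle
#' waveforms recorded in the same trial; waveforms from different trials
#' decorrelate. This function computes both distributions: within-trial
#' coefficients over all segment pairs of `trial_a`, and cross-trial
#' coefficients pairing each segment waveform of `trial_a` with the other
#' segment's waveform from `trial_b` (trials are truncated to their common
#' length).
#'
#' @param trial_a,trial_b [gait_recording()] objects.
#' @param segments segment names to include (default: all ten).
#' @param max_lag maximum lag in seconds.
#' @param cfg a [skeleton_config()].
#' @return Object of class `"trial_comparison"`: coefficient vectors
#'   `same` and `cross`, a long pair table with a `group` column, and a
#'   `summary` data frame (n, median, quartiles per group) suitable for a
#'   box plot.
#' @export
compare_trials <- function(trial_a, trial_b,
                           segments = names(default_sensor_map()),
                           max_lag = 1.5, cfg = skeleton_config()) {
  stopifnot(inherits(trial_a, "gait_recording"),
            inherits(trial_b, "gait_recording"))
  n <- min(n_frames(trial_a), n_frames(trial_b))
  if (n < 4L) stop_validation("trials too short to compare")
  same <- coordination_matrix(trial_a, segments, max_lag, cfg)
  ser_a <- coordination_series(trial_a, segments, cfg)
  ser_b <- coordination_series(trial_b, segments, cfg)
  k <- length(segments)
  cross <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- xcorr_max(ser_a[[i]][seq_len(n)], ser_b[[j]][seq_len(n)],
                     trial_a$rate, max_lag)
      cross[[length(cross) + 1L]] <- data.frame(
        segment_a = segments[i], segment_b = segments[j],
        coefficient = r$coefficient, lag_s = r$lag)
    }
  }
  cross <- do.call(rbind, cross)
  tab <- rbind(cbind(same$pairs, group = "same-trial"),
               cbind(cross, group = "cross-trial"))
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  sm <- do.call(rbind, lapply(split(tab$coefficient, tab$group), function(v) {
    q <- qs(v)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
  sm <- cbind(group = rownames(sm), sm)
  rownames(sm) <- NULL
  structure(list(same = same$pairs$coefficient, cross = cross$coefficient,
                 pairs = tab, summary = sm),
            class = "trial_comparison")
}

#' @export
print.trial_comparison <- function(x, ...) {
  cat("<trial_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Box plot of same-trial vs cross-trial coordination coefficients
#'
#' @param x a [compare_trials()] result.
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, `x`.
#' @export
plot.trial_comparison <- function(x, ...) {
  graphics::boxplot(list(`same trial` = x$same, `cross trial` = x$cross),
                    ylab = "cross-correlation coefficient", ...)
  invisible(x)
}
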