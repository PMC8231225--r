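#' Detect local maxima of an angle series
#'
#' A peak is a sample strictly greater than the nearest differing values on
#' both sides (plateaus count once, at their earliest index). Peaks may be
#' filtered by topographic prominence (height above the higher of the two
#' flanking minima, walking outward until a higher sample or the series
#' edge) and by a minimum separation; when two candidates are closer than
#' `min_separation` the higher one is kept (ties: the earlier). The
#' procedure is deterministic.
#'
#' @param x numeric angle series (degrees); must hold at least 3 samples.
#' @param times sample times in seconds (default: sample index).
#' @param min_separation minimum time between retained peaks, in the units
#'   of `times`; 0 disables the filter.
#' @param min_prominence minimum prominence in the units of `x`; 0 disables
#'   the filter.
#' @return Integer vector of peak indices, increasing. Constant or
#'   too-short series yield `integer(0)`.
#' @export
find_peaks <- function(x, times = seq_along(x), min_separation = 0,
                       min_prominence = 0) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || anyNA(x)) {
    if (anyNA(x)) stop_validation("series contains NA; interpolate gaps first")
    return(integer(0))
  }
  if (length(times) != n) stop_validation("times must match the series length")
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(cand, function(p) {
      lo_l <- x[p]
      k <- p
      while (k > 1L && x[k - 1L] <= x[p]) {
        k <- k - 1L
        if (x[k] < lo_l) lo_l <- x[k]
      }
      lo_r <- x[p]
      k <- p
      while (k < n && x[k + 1L] <= x[p]) {
        k <- k + 1L
        if (x[k] < lo_r) lo_r <- x[k]
      }
      x[p] - max(lo_l, lo_r)
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
    if (length(cand) == 0L) return(integer(0))
  }
  if (min_separation > 0 && length(cand) > 1L) {
    ord <- cand[order(-x[cand], cand)]
    kept <- integer(0)
    for (p in ord) {
      if (all(abs(times[p] - times[kept]) >= min_separation)) kept <- c(kept, p)
    }
    cand <- sort(kept)
  }
  cand
}

#' Detect local minima of an angle series
#'
#' Exactly [find_peaks()] applied to the negated series.
#'
#' @inheritParams find_peaks
#' @return Integer vector of trough indices, increasing.
#' @export
find_troughs <- function(x, times = seq_along(x), min_separation = 0,
                         min_prominence = 0) {
  find_peaks(-as.numeric(x), times, min_separation, min_prominence)
}

# Linear interpolation of NA gaps (ends extended with the nearest value),
# then centred moving-average smoothing with edge shrink. Used to condition
# the raw angle series before event detection; find_peaks itself stays raw.
prepare_series <- function(x, times, smooth_window = 0) {
  x <- as.numeric(x)
  if (anyNA(x)) {
    ok <- !is.na(x)
    if (sum(ok) < 2L) stop_validation("series has fewer than 2 observed samples")
    x <- stats::approx(times[ok], x[ok], xout = times, rule = 2)$y
  }
  if (smooth_window > 0) {
    h <- smooth_halfwidth(times, smooth_window)
    if (h > 0L) {
      cs <- cumsum(c(0, x))
      n <- length(x)
      lo <- pmax(1L, seq_len(n) - h)
      hi <- pmin(n, seq_len(n) + h)
      x <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
  }
  x
}

smooth_halfwidth <- function(times, smooth_window) {
  dt <- stats::median(diff(times))
  w <- max(1L, round(smooth_window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  (w - 1L) %/% 2L
}

# Smoothing a waveform whose extrema have unequal left/right slopes (as
# gait angle cycles do) shifts the smoothed extremum towards the shallower
# side, and a raw argmax under noise is biased the same way (flat-side
# samples win more often). A least-squares parabola over a symmetric
# window around the detected extremum is unbiased under i.i.d. noise and
# nearly unbiased for the asymmetric shape; its vertex gives a sub-sample
# event time and a low-noise estimate of the angle at the event.
refine_extrema <- function(idx, raw, times, h, maxima = TRUE) {
  n <- length(raw)
  k <- length(idx)
  out <- list(time = times[idx], value = raw[idx], index = idx)
  if (h <= 0L || k == 0L) return(out)
  for (m in seq_len(k)) {
    p <- idx[m]
    rng <- max(1L, p - h):min(n, p + h)
    if (length(rng) < 5L) next
    tt <- times[rng] - times[p]
    co <- stats::lm.fit(cbind(1, tt, tt^2), raw[rng])$coefficients
    a <- co[3]
    if (!is.finite(a) || (maxima && a >= 0) || (!maxima && a <= 0)) next
    tv <- -co[2] / (2 * a)
    tv <- min(max(tv, tt[1]), tt[length(tt)])  # clamp to the fit window
    out$time[m] <- times[p] + tv
    out$value[m] <- co[1] + co[2] * tv + a * tv^2
    out$index[m] <- rng[which.min(abs(tt - tv))]
  }
  out
}

#' Extract gait events from left and right angle series
#'
#' Implements the event model of the analysis: initial heel contact occurs
#' when the monitored leg angle is maximal, toe-off when it is minimal.
#' Both series are conditioned first (linear interpolation across
#' missing-frame gaps, then moving-average smoothing) and extrema are
#' detected per leg with the separation/prominence filters of
#' [find_peaks()]; each detected extremum is then snapped to the raw-series
#' extremum inside the smoothing half-window, cancelling the timing bias
#' smoothing introduces on asymmetric gait cycles.
#'
#' @param left,right numeric angle series (degrees) for the two legs,
#'   sharing the time base `times`; `NA` marks missing frames.
#' @param times sample times in seconds.
#' @param min_separation minimum time between events of the same kind on
#'   one leg (seconds); default 0.4 s, below any plausible stride period.
#' @param min_prominence minimum extremum prominence (degrees); default 5,
#'   rejecting sensor-noise wiggles.
#' @param smooth_window moving-average window in seconds applied before
#'   detection (default 0.15 s); 0 disables smoothing.
#' @return An object of class `"gait_events"`: heel-contact times
#'   `H_left`/`H_right` and toe-off times `T_left`/`T_right` (seconds,
#'   sub-sample resolution), their nearest sample indices, the fitted
#'   angles at each event (`angle_H_*`, `angle_T_*`, degrees), peak counts
#'   `n_left`/`n_right`, trial duration `t_total` (last minus first sample
#'   time), the conditioned series and the time base. Raises an
#'   insufficient-cycles error when a leg shows fewer than 2 heel
#'   contacts.
#' @export
extract_events <- function(left, right, times, min_separation = 0.4,
                           min_prominence = 5, smooth_window = 0.15) {
  if (length(left) != length(times) || length(right) != length(times)) {
    stop_validation("left, right and times must have equal length")
  }
  if (length(times) < 3L) {
    stop_insufficient_cycles("series too short for event detection")
  }
  if (min_separation <= 0) stop_validation("min_separation must be > 0")
  raw_l <- prepare_series(left, times, 0)
  raw_r <- prepare_series(right, times, 0)
  ls <- prepare_series(left, times, smooth_window)
  rs <- prepare_series(right, times, smooth_window)
  h <- if (smooth_window > 0) smooth_halfwidth(times, smooth_window) else 0L
  ev <- list()
  for (leg in c("left", "right")) {
    s <- if (leg == "left") ls else rs
    raw <- if (leg == "left") raw_l else raw_r
    pk <- find_peaks(s, times, min_separation, min_prominence)
    tr <- find_troughs(s, times, min_separation, min_prominence)
    if (length(pk) < 2L) {
      stop_insufficient_cycles(
        "fewer than 2 heel contacts detected on the %s leg; trial too short or signal too flat",
        leg)
    }
    rp <- refine_extrema(pk, raw, times, h, maxima = TRUE)
    rt <- refine_extrema(tr, raw, times, h, maxima = FALSE)
    ev[[paste0("H_", leg)]] <- rp$time
    ev[[paste0("T_", leg)]] <- rt$time
    ev[[paste0("idx_H_", leg)]] <- rp$index
    ev[[paste0("idx_T_", leg)]] <- rt$index
    ev[[paste0("angle_H_", leg)]] <- rp$value
    ev[[paste0("angle_T_", leg)]] <- rt$value
    ev[[paste0("n_", leg)]] <- length(pk)
  }
  ev$t_total <- times[length(times)] - times[1]
  ev$times <- times
  ev$series_left <- ls
  ev$series_right <- rs
  structure(ev, class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d left / %d right heel contacts over %.2f s\n",
              x$n_left, x$n_right, x$t_total))
  cat(sprintf("  toe-offs: %d left / %d right\n",
              length(x$T_left), length(x$T_right)))
  invisible(x)
}
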