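rec_colnames <- function() {
  paste0("s", rep(0:9, each = 4), ".", rep(c("w", "x", "y", "z"), 10))
}

#' Ten-sensor quaternion recording matrix
#'
#' The central data container: a timestamped n x 40 matrix of quaternion
#' components, four columns `(w, x, y, z)` per sensor in sensor-ID order
#' 0..9, plus a per-sensor presence mask marking frames in which a sensor's
#' packet was lost.
#'
#' @param timestamps numeric vector of frame times in seconds, non-decreasing.
#' @param values n x 40 numeric matrix of quaternion components; cells of
#'   absent sensors are `NA`.
#' @param mask optional n x 10 logical matrix (`TRUE` = sensor present that
#'   frame); derived from `NA` patterns in `values` when omitted.
#' @param rate sampling rate in Hz (default 59, the system rate at which
#'   ten sensors stream reliably).
#' @param subject,trial free-text labels carried in the file header.
#' @return An object of class `"gait_recording"`.
#' @export
gait_recording <- function(timestamps, values, mask = NULL, rate = 59,
                           subject = "", trial = "") {
  timestamps <- as.numeric(timestamps)
  values <- as.matrix(values)
  n <- length(timestamps)
  if (ncol(values) != 40L) {
    stop_format("recording must have exactly 40 quaternion value columns, got %d",
                ncol(values))
  }
  if (nrow(values) != n) {
    stop_format("timestamps (%d) and value rows (%d) differ", n, nrow(values))
  }
  if (n > 1 && any(diff(timestamps) < 0)) {
    stop_format("timestamps must be non-decreasing")
  }
  if (!is.numeric(rate) || rate <= 0) stop_validation("sampling rate must be > 0")
  if (is.null(mask)) {
    mask <- !is.na(values[, seq(1, 40, by = 4), drop = FALSE])
  }
  mask <- as.matrix(mask)
  if (!all(dim(mask) == c(n, 10L))) {
    stop_format("mask must be n x 10")
  }
  colnames(values) <- rec_colnames()
  colnames(mask) <- paste0("s", 0:9)
  structure(list(timestamps = timestamps, values = values,
                 mask = matrix(as.logical(mask), n, 10,
                               dimnames = dimnames(mask)),
                 rate = rate, subject = subject, trial = trial),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  n <- length(x$timestamps)
  dur <- if (n > 0) x$timestamps[n] - x$timestamps[1] else 0
  cat(sprintf("<gait_recording> %d frames x 40 columns, %.1f Hz, %.2f s\n",
              n, x$rate, dur))
  if (n > 0) {
    cat(sprintf("  present cells: %.1f%%  subject='%s' trial='%s'\n",
                100 * mean(x$mask), x$subject, x$trial))
  }
  invisible(x)
}

#' Number of frames in a recording
#' @param rec a [gait_recording()].
#' @return Integer frame count.
#' @export
n_frames <- function(rec) length(rec$timestamps)

#' Parse one serial-dialect quaternion packet line
#'
#' Each packet is a comma-separated line `timestamp,sensor_id,w,x,y,z`:
#' the sensor ID (0-9) followed by the four quaternion components, with a
#' receiver-side timestamp in seconds. The quaternion is normalised on
#' ingest; a norm further than 0.02 from 1 (the sensor-noise allowance) is
#' rejected.
#'
#' @param line character scalar, one packet.
#' @param line_number optional line number used in error messages.
#' @return List with `timestamp`, `sensor_id`, `w`, `x`, `y`, `z`.
#' @export
parse_packet <- function(line, line_number = NA) {
  where <- if (is.na(line_number)) "" else sprintf(" (line %s)", line_number)
  parts <- strsplit(trimws(line), ",", fixed = TRUE)[[1]]
  if (length(parts) != 6L) {
    stop_format("packet%s: expected 6 comma-separated fields, got %d",
                where, length(parts))
  }
  num <- suppressWarnings(as.numeric(parts))
  if (anyNA(num)) stop_format("packet%s: non-numeric field '%s'",
                              where, parts[which(is.na(num))[1]])
  id <- num[2]
  if (id != round(id) || id < 0 || id > 9) {
    stop_format("packet%s: sensor ID must be an integer in 0..9, got %s",
                where, parts[2])
  }
  q <- num[3:6]
  nrm <- sqrt(sum(q^2))
  if (nrm < 1e-12) stop_format("packet%s: zero-norm quaternion", where)
  if (abs(nrm - 1) > 0.02) {
    stop_format("packet%s: quaternion norm %.4f outside the 0.02 sensor tolerance",
                where, nrm)
  }
  q <- q / nrm
  list(timestamp = num[1], sensor_id = as.integer(id),
       w = q[1], x = q[2], y = q[3], z = q[4])
}

#' Read a packet stream file into a packet table
#'
#' Lines starting with `#` and blank lines are skipped. Malformed lines
#' raise a format error naming the line number.
#'
#' @param path path to a line-oriented packet file
#'   (`timestamp,sensor_id,w,x,y,z` per line).
#' @return Data frame with columns `timestamp`, `sensor_id`, `w`, `x`, `y`,
#'   `z`; quaternions normalised.
#' @export
read_packets <- function(path) {
  if (!file.exists(path)) stop_format("packet file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    return(data.frame(timestamp = numeric(0), sensor_id = integer(0),
                      w = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  parts <- strsplit(trimws(lines[keep]), ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    stop_format("packet line %d: expected 6 fields, got %d",
                keep[which(nf != 6L)[1]], nf[nf != 6L][1])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 6, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop_format("packet line %d: non-numeric field", keep[bad])
  }
  ids <- m[, 2]
  if (any(ids != round(ids) | ids < 0 | ids > 9)) {
    bad <- which(ids != round(ids) | ids < 0 | ids > 9)[1]
    stop_format("packet line %d: sensor ID must be an integer in 0..9", keep[bad])
  }
  nrm <- sqrt(rowSums(m[, 3:6, drop = FALSE]^2))
  if (any(nrm < 1e-12)) {
    stop_format("packet line %d: zero-norm quaternion", keep[which(nrm < 1e-12)[1]])
  }
  if (any(abs(nrm - 1) > 0.02)) {
    stop_format("packet line %d: quaternion norm outside the 0.02 sensor tolerance",
                keep[which(abs(nrm - 1) > 0.02)[1]])
  }
  data.frame(timestamp = m[, 1], sensor_id = as.integer(ids),
             w = m[, 3] / nrm, x = m[, 4] / nrm, y = m[, 5] / nrm,
             z = m[, 6] / nrm)
}

#' Assemble timestamped packets into a recording matrix
#'
#' Packets are binned onto a regular frame grid of width `1/rate` anchored
#' at the earliest timestamp. Sensors with no packet in a bin are masked as
#' missing; when a sensor delivers several packets in one bin the latest
#' wins.
#'
#' @param packets data frame with columns `timestamp`, `sensor_id`, `w`,
#'   `x`, `y`, `z` (as from [read_packets()]).
#' @param rate sampling rate in Hz (default 59).
#' @param subject,trial labels stored in the recording metadata.
#' @return A [gait_recording()]; empty input yields an empty recording.
#' @export
assemble_frames <- function(packets, rate = 59, subject = "", trial = "") {
  if (nrow(packets) == 0) {
    return(gait_recording(numeric(0), matrix(numeric(0), 0, 40),
                          matrix(logical(0), 0, 10), rate, subject, trial))
  }
  o <- order(packets$timestamp)
  packets <- packets[o, , drop = FALSE]
  t0 <- packets$timestamp[1]
  bin <- as.integer(floor((packets$timestamp - t0) * rate + 0.5))
  n <- max(bin) + 1L
  values <- matrix(NA_real_, n, 40)
  mask <- matrix(FALSE, n, 10)
  id <- packets$sensor_id
  base <- 4L * id
  # duplicate (bin, sensor) pairs: rows are in time order, so the later
  # assignment overwrites the earlier one (last-write-wins)
  for (k in 1:4) {
    values[cbind(bin + 1L, base + k)] <- packets[[c("w", "x", "y", "z")[k]]]
  }
  mask[cbind(bin + 1L, id + 1L)] <- TRUE
  gait_recording(t0 + (0:(n - 1L)) / rate, values, mask, rate, subject, trial)
}

#' Write a recording to its plain-text file format
#'
#' The format is line-oriented: `# key=value` header lines (format tag,
#' rate, subject, trial, column order), then one comma-separated row per
#' frame holding the timestamp followed by the 40 quaternion components.
#' Components are stored with exactly four decimal places (the storage
#' precision of the acquisition system); missing cells are written as `NA`.
#'
#' @param rec a [gait_recording()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  header <- c("# gaitq_recording v1",
              sprintf("# rate=%.6g", rec$rate),
              sprintf("# subject=%s", rec$subject),
              sprintf("# trial=%s", rec$trial),
              paste0("# columns=timestamp,", paste(rec_colnames(), collapse = ",")))
  vals <- matrix(sprintf("%.4f", rec$values), nrow(rec$values), 40)
  vals[is.na(rec$values)] <- "NA"
  rows <- paste(sprintf("%.6f", rec$timestamps),
                apply(vals, 1, paste, collapse = ","), sep = ",")
  if (n_frames(rec) == 0) rows <- character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path to a recording file.
#' @return A [gait_recording()]. Raises a format error on a missing or
#'   corrupt header, a wrong column count, or decreasing timestamps.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_format("recording file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0 || !grepl("gaitq_recording", hdr[1])) {
    stop_format("missing or corrupt recording header in %s", path)
  }
  kv <- sub("^#\\s*", "", hdr[-1])
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  if (is.null(meta$rate)) stop_format("recording header lacks rate")
  rate <- suppressWarnings(as.numeric(meta$rate))
  if (is.na(rate) || rate <= 0) stop_format("invalid rate in recording header")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    return(gait_recording(numeric(0), matrix(numeric(0), 0, 40), NULL, rate,
                          meta$subject %||% "", meta$trial %||% ""))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 41L)) {
    stop_format("recording row %d has %d columns; expected timestamp + 40 values",
                which(nf != 41L)[1], nf[nf != 41L][1])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 41, byrow = TRUE)
  ts <- m[, 1]
  if (anyNA(ts)) stop_format("non-numeric timestamp in recording body")
  if (length(ts) > 1 && any(diff(ts) < 0)) {
    stop_format("timestamps must be non-decreasing")
  }
  values <- m[, -1, drop = FALSE]
  # a sensor is present in a frame iff all four of its components are present
  pres <- !is.na(values)
  for (s in 0:9) {
    blk <- pres[, 4 * s + 1:4, drop = FALSE]
    partial <- rowSums(blk) %in% 1:3
    if (any(partial)) {
      stop_format("recording row %d: sensor %d has a partially missing quaternion",
                  which(partial)[1], s)
    }
  }
  gait_recording(ts, values, NULL, rate, meta$subject %||% "", meta$trial %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame-by-frame playback iterator
#'
#' Returns a closure that yields frames in timestamp order; the nominal
#' inter-frame interval is divided by `speed` (2 = twice as fast). No frame
#' is ever dropped.
#'
#' @param rec a non-empty [gait_recording()].
#' @param speed playback speed factor, `> 0`.
#' @return A function of no arguments returning, per call, a list with
#'   `frame` (index), `timestamp`, `interval` (scaled seconds until the
#'   next frame; `NA` for the last), `quats` (10 x 4 matrix) and `present`
#'   (logical 10), then `NULL` once exhausted.
#' @export
playback <- function(rec, speed = 1) {
  stopifnot(inherits(rec, "gait_recording"))
  if (n_frames(rec) == 0) stop_validation("cannot play back an empty recording")
  if (!is.numeric(speed) || speed <= 0) stop_validation("speed factor must be > 0")
  i <- 0L
  n <- n_frames(rec)
  function() {
    i <<- i + 1L
    if (i > n) return(NULL)
    gap <- if (i < n) (rec$timestamps[i + 1L] - rec$timestamps[i]) / speed else NA_real_
    list(frame = i, timestamp = rec$timestamps[i], interval = gap,
         quats = matrix(rec$values[i, ], 10, 4, byrow = TRUE,
                        dimnames = list(paste0("s", 0:9), c("w", "x", "y", "z"))),
         present = rec$mask[i, ])
  }
}
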