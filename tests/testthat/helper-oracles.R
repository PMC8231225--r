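# Independent oracles used across the suite.

# Rotation matrix built directly from quaternion components (textbook
# direction-cosine form), independent of the package's sandwich product.
rotmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Brute-force O(n) local-extrema scan: samples strictly greater than both
# neighbours.
brute_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

rand_unit_quat <- function() {
  v <- stats::rnorm(4)
  v <- v / sqrt(sum(v^2))
  quaternion(v[1], v[2], v[3], v[4])
}

# 10-sensor recording in which every segment follows the given angle
# series (degrees, rotation about the lateral axis).
recording_from_angles <- function(angles_by_segment, rate = 59) {
  n <- nrow(angles_by_segment)
  vals <- angles_to_quaternions(angles_by_segment)
  gait_recording((0:(n - 1)) / rate, vals, rate = rate)
}

# Minimal gait_events object from explicit event times, for unit-testing
# the parameter formulas in isolation.
make_events <- function(H_left, T_left, H_right, T_right, t_total) {
  structure(list(
    H_left = H_left, T_left = T_left, H_right = H_right, T_right = T_right,
    n_left = length(H_left), n_right = length(H_right), t_total = t_total
  ), class = "gait_events")
}
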