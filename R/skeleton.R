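#' Segment names and default sensor mapping
#'
#' The ten body-worn sensors carry IDs 0-9. The default assignment follows
#' the deployment on front arms, upper arms, thighs, shanks and feet:
#' left arm (upper 0, fore 1), right arm (upper 2, fore 3), left leg
#' (thigh 4, shank 5, foot 6), right leg (thigh 7, shank 8, foot 9).
#'
#' @return Named integer vector mapping segment name to sensor ID.
#' @export
default_sensor_map <- function() {
  c(upper_arm_l = 0L, fore_arm_l = 1L,
    upper_arm_r = 2L, fore_arm_r = 3L,
    thigh_l = 4L, shank_l = 5L, foot_l = 6L,
    thigh_r = 7L, shank_r = 8L, foot_r = 9L)
}

limb_segments <- list(
  arm_l = c("upper_arm_l", "fore_arm_l"),
  arm_r = c("upper_arm_r", "fore_arm_r"),
  leg_l = c("thigh_l", "shank_l", "foot_l"),
  leg_r = c("thigh_r", "shank_r", "foot_r")
)

limb_joints <- list(
  arm_l = c("shoulder_l", "elbow_l", "wrist_l"),
  arm_r = c("shoulder_r", "elbow_r", "wrist_r"),
  leg_l = c("hip_l", "knee_l", "ankle_l", "toe_l"),
  leg_r = c("hip_r", "knee_r", "ankle_r", "toe_r")
)

#' Skeleton configuration for the 10-segment body model
#'
#' The human model is a ball-and-stick skeleton: limb segments of fixed
#' length whose orientations come from the ten sensors. Each segment is
#' oriented independently by its own sensor (absolute orientation, no
#' parent-child composition) and chained by translation, proximal to
#' distal. Torso root joints (shoulders, hips) are static configuration:
#' only the limbs carry sensors.
#'
#' @param lengths named numeric vector of segment lengths in metres, names
#'   `upper_arm`, `fore_arm`, `thigh`, `shank`, `foot` (shared left/right).
#' @param shoulder_width,hip_width distance between left/right root joints
#'   (metres).
#' @param shoulder_height,hip_height height of the root joints above the
#'   ground origin (metres).
#' @param sensor_map named integer vector, segment name -> sensor ID; must
#'   be a bijection onto `0:9` over the ten segment names.
#' @return An object of class `"skeleton_config"`.
#' @export
skeleton_config <- function(lengths = c(upper_arm = 0.30, fore_arm = 0.28,
                                        thigh = 0.42, shank = 0.42,
                                        foot = 0.25),
                            shoulder_width = 0.40, hip_width = 0.20,
                            shoulder_height = 1.40, hip_height = 0.90,
                            sensor_map = default_sensor_map()) {
  need <- c("upper_arm", "fore_arm", "thigh", "shank", "foot")
  if (!all(need %in% names(lengths))) {
    stop_validation("lengths must name all of: %s", paste(need, collapse = ", "))
  }
  if (any(lengths[need] <= 0)) stop_validation("all segment lengths must be > 0")
  segs <- names(default_sensor_map())
  if (!setequal(names(sensor_map), segs) ||
      !setequal(as.integer(sensor_map), 0:9) ||
      anyDuplicated(as.integer(sensor_map)) > 0) {
    stop_validation("sensor_map must be a bijection from the 10 segment names onto IDs 0..9")
  }
  seg_len <- c(upper_arm_l = unname(lengths["upper_arm"]),
               fore_arm_l = unname(lengths["fore_arm"]),
               upper_arm_r = unname(lengths["upper_arm"]),
               fore_arm_r = unname(lengths["fore_arm"]),
               thigh_l = unname(lengths["thigh"]),
               shank_l = unname(lengths["shank"]),
               foot_l = unname(lengths["foot"]),
               thigh_r = unname(lengths["thigh"]),
               shank_r = unname(lengths["shank"]),
               foot_r = unname(lengths["foot"]))
  roots <- list(
    shoulder_l = c(0, shoulder_height, -shoulder_width / 2),
    shoulder_r = c(0, shoulder_height, shoulder_width / 2),
    hip_l = c(0, hip_height, -hip_width / 2),
    hip_r = c(0, hip_height, hip_width / 2)
  )
  structure(list(segment_lengths = seg_len, roots = roots,
                 sensor_map = sensor_map[segs]),
            class = "skeleton_config")
}

#' @export
print.skeleton_config <- function(x, ...) {
  cat("<skeleton_config> 10 segments\n")
  cat("  lengths (m):",
      paste(sprintf("%s=%.2f", names(x$segment_lengths), x$segment_lengths),
            collapse = " "), "\n")
  invisible(x)
}

#' Distal endpoint of a rigid segment
#'
#' Places a segment of the given length at `origin` and rotates its rest
#' direction `(0, -1, 0)` by the sensor orientation.
#'
#' @param q unit [quaternion()] for the segment.
#' @param origin numeric length-3 proximal joint position (metres).
#' @param length segment length in metres, `> 0`.
#' @return Distal joint position, `origin + length * R(q) (0,-1,0)`.
#' @export
segment_endpoint <- function(q, origin, length) {
  if (!is.numeric(length) || length <= 0) {
    stop_validation("segment length must be > 0")
  }
  as.numeric(origin) + length * quat_rotate(q, c(0, -1, 0))
}

#' Reconstruct one frame's full-body pose
#'
#' Chains each limb proximal to distal (shoulder -> elbow -> wrist;
#' hip -> knee -> ankle -> toe), translating every segment to the end of
#' the previous one. Each segment uses its own sensor's absolute
#' orientation. A limb with any missing segment cannot be reconstructed
#' and is flagged invalid with its joints unset.
#'
#' @param quats 10 x 4 numeric matrix of quaternion components `(w,x,y,z)`,
#'   row `i` holding sensor ID `i - 1`.
#' @param present logical vector of length 10: which sensors delivered a
#'   sample this frame.
#' @param cfg a [skeleton_config()].
#' @return An object of class `"gait_pose"`: list with `joints` (data frame
#'   of joint name and x, y, z in metres; `NA` for invalid limbs) and
#'   `limb_valid` (named logical for arm_l, arm_r, leg_l, leg_r).
#' @export
reconstruct_pose <- function(quats, present = rep(TRUE, 10), cfg = skeleton_config()) {
  quats <- as.matrix(quats)
  if (!all(dim(quats) == c(10L, 4L))) {
    stop_validation("quats must be a 10 x 4 matrix (sensors 0..9, components w,x,y,z)")
  }
  if (length(present) != 10L) stop_validation("present must have length 10")
  map <- cfg$sensor_map
  joint_names <- c("shoulder_l", "shoulder_r", "hip_l", "hip_r",
                   unlist(lapply(limb_joints, function(j) j[-1]), use.names = FALSE))
  pos <- matrix(NA_real_, length(joint_names), 3,
                dimnames = list(joint_names, c("x", "y", "z")))
  for (r in names(cfg$roots)) pos[r, ] <- cfg$roots[[r]]
  limb_valid <- c(arm_l = FALSE, arm_r = FALSE, leg_l = FALSE, leg_r = FALSE)
  root_of <- c(arm_l = "shoulder_l", arm_r = "shoulder_r",
               leg_l = "hip_l", leg_r = "hip_r")
  for (limb in names(limb_segments)) {
    segs <- limb_segments[[limb]]
    ids <- map[segs] + 1L           # sensor ID -> matrix row
    ok <- all(present[ids]) && !anyNA(quats[ids, , drop = FALSE])
    if (!ok) next
    limb_valid[limb] <- TRUE
    at <- pos[root_of[limb], ]
    joints <- limb_joints[[limb]][-1]
    for (k in seq_along(segs)) {
      q <- quat_normalize(quaternion(quats[ids[k], 1], quats[ids[k], 2],
                                     quats[ids[k], 3], quats[ids[k], 4]))
      at <- segment_endpoint(q, at, cfg$segment_lengths[segs[k]])
      pos[joints[k], ] <- at
    }
  }
  structure(list(
    joints = data.frame(joint = rownames(pos), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], row.names = NULL),
    limb_valid = limb_valid
  ), class = "gait_pose")
}

#' @export
print.gait_pose <- function(x, ...) {
  cat("<gait_pose> valid limbs:",
      paste(names(x$limb_valid)[x$limb_valid], collapse = ", "), "\n")
  invisible(x)
}

#' Knee (or elbow) angle between two adjacent segments
#'
#' The included angle between the two segments' world directions (rest
#' direction rotated by each sensor's orientation), i.e. the flexion angle
#' at the joint connecting them.
#'
#' @param q_thigh,q_shank unit quaternions for the proximal and distal
#'   segment.
#' @return Angle in degrees in `[0, 180]`; symmetric in its arguments.
#' @export
knee_angle <- function(q_thigh, q_shank) {
  d1 <- quat_rotate(q_thigh, c(0, -1, 0))
  d2 <- quat_rotate(q_shank, c(0, -1, 0))
  dp <- sum(d1 * d2)
  acos(min(1, max(-1, dp))) * 180 / pi
}

#' Joint-angle time series from a recording
#'
#' Extracts, per frame, either the sagittal-plane angle of the shank sensor
#' (the default event signal) or the knee flexion angle between thigh and
#' shank. Frames in which a required sensor is missing yield `NA` gaps.
#'
#' @param rec a [gait_recording()].
#' @param leg `"left"` or `"right"`.
#' @param mode `"shank_sagittal"` (default) or `"knee_flexion"`.
#' @param cfg a [skeleton_config()] supplying the sensor map.
#' @return Data frame with columns `time` (seconds) and `angle` (degrees),
#'   one row per frame.
#' @export
angle_series <- function(rec, leg = c("left", "right"),
                         mode = c("shank_sagittal", "knee_flexion"),
                         cfg = skeleton_config()) {
  stopifnot(inherits(rec, "gait_recording"))
  leg <- match.arg(leg)
  mode <- match.arg(mode)
  sfx <- if (leg == "left") "_l" else "_r"
  map <- cfg$sensor_map
  need <- if (mode == "shank_sagittal") paste0("shank", sfx)
          else paste0(c("thigh", "shank"), sfx)
  if (!all(need %in% names(map))) {
    stop_validation("recording/sensor map lacks segments: %s",
                    paste(need, collapse = ", "))
  }
  qm_of <- function(seg) {
    id <- map[[seg]]
    m <- rec$values[, 4 * id + 1:4, drop = FALSE]
    m[!rec$mask[, id + 1L], ] <- NA_real_
    m
  }
  if (mode == "shank_sagittal") {
    ang <- sagittal_angle_mat(qm_of(need))
  } else {
    d1 <- rotated_down_mat(qm_of(need[1]))
    d2 <- rotated_down_mat(qm_of(need[2]))
    dp <- rowSums(d1 * d2)
    ang <- acos(pmin(1, pmax(-1, dp))) * 180 / pi
  }
  data.frame(time = rec$timestamps, angle = as.numeric(ang))
}

#' Per-frame joint positions for all frames of a recording
#'
#' Replays a recording through the body model and returns one row per frame
#' and joint, the plain-text analogue of the interactive playback view.
#'
#' @param rec a [gait_recording()].
#' @param cfg a [skeleton_config()].
#' @return Data frame with columns `frame`, `time`, `joint`, `x`, `y`, `z`
#'   (metres); joints of invalid limbs carry `NA` coordinates.
#' @export
pose_table <- function(rec, cfg = skeleton_config()) {
  stopifnot(inherits(rec, "gait_recording"))
  n <- length(rec$timestamps)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    qm <- matrix(rec$values[i, ], nrow = 10, ncol = 4, byrow = TRUE)
    pose <- reconstruct_pose(qm, rec$mask[i, ], cfg)
    j <- pose$joints
    out[[i]] <- data.frame(frame = i, time = rec$timestamps[i],
                           joint = j$joint, x = j$x, y = j$y, z = j$z)
  }
  do.call(rbind, out)
}

#' Export reconstructed poses to a tab-separated file
#'
#' @param rec a [gait_recording()].
#' @param path output file path.
#' @param cfg a [skeleton_config()].
#' @return Invisibly, the exported data frame.
#' @export
export_pose <- function(rec, path, cfg = skeleton_config()) {
  tab <- pose_table(rec, cfg)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
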