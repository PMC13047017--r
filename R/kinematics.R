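#' @title Per-frame kinematic features
#' @description 2D sagittal-plane geometry computed from landmark pixel
#'   coordinates with standard vector operations. All angles are projections
#'   into the lateral viewing plane; distances are normalised by trunk length
#'   (mid-shoulder to mid-hip) so features are invariant to camera distance.
#' @name kinematics
NULL

RAD2DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

#' Inter-joint angle at a vertex
#'
#' Angle at vertex `b` between rays `b -> a` and `b -> c`, in degrees,
#' in \[0, 180\].
#'
#' @param a,b,c Numeric 2D points (x, y).
#' @return Angle in degrees.
#' @export
#' @examples
#' joint_angle(c(1, 0), c(0, 0), c(0, 1))  # 90
joint_angle <- function(a, b, c) {
  u <- as.numeric(a[1:2]) - as.numeric(b[1:2])
  v <- as.numeric(c[1:2]) - as.numeric(b[1:2])
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: zero-length ray at angle vertex", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * RAD2DEG
}

#' Flexion from an inter-joint angle
#'
#' The package-wide flexion convention: `F = 180 - inter-joint angle`, so a
#' fully extended joint has flexion 0 and a deeply bent joint a large value.
#'
#' @param inter_joint_angle Angle in degrees, in \[0, 180\].
#' @return Flexion in degrees.
#' @export
flexion <- function(inter_joint_angle) {
  if (any(!is.finite(inter_joint_angle)) ||
      any(inter_joint_angle < 0 | inter_joint_angle > 180))
    stop("inter-joint angle must lie in [0, 180]", call. = FALSE)
  180 - inter_joint_angle
}

#' Inclination of a segment from the vertical
#'
#' Unsigned angle between the vector `p_top -> p_bottom` and the image-down
#' direction (+y), in degrees, in \[0, 180\]. 0 means the segment hangs
#' vertically. The camera is assumed level, so image-vertical is the
#' gravity vertical.
#'
#' @param p_top,p_bottom Numeric 2D points (x, y), y increasing downward.
#' @return Angle in degrees.
#' @export
segment_inclination <- function(p_top, p_bottom) {
  v <- as.numeric(p_bottom[1:2]) - as.numeric(p_top[1:2])
  n <- vnorm(v)
  if (n == 0)
    stop("degenerate geometry: coincident segment endpoints", call. = FALSE)
  acos(min(1, max(-1, v[2] / n))) * RAD2DEG
}

midpoint2 <- function(p, q) (as.numeric(p[1:2]) + as.numeric(q[1:2])) / 2

mid_shoulder <- function(frame)
  midpoint2(frame["left_shoulder", ], frame["right_shoulder", ])
mid_hip <- function(frame)
  midpoint2(frame["left_hip", ], frame["right_hip", ])

trunk_length_px <- function(frame) {
  vnorm(mid_shoulder(frame) - mid_hip(frame))
}

#' Trunk inclination from vertical
#'
#' Inclination of the torso axis, the segment from the shoulder midpoint
#' down to the hip midpoint; 0 degrees is upright.
#'
#' @param frame A `landmark_frame`.
#' @return Angle in degrees.
#' @export
trunk_inclination <- function(frame) {
  segment_inclination(mid_shoulder(frame), mid_hip(frame))
}

#' Facing direction along the image x axis
#'
#' Sign of (nose_x - mid-hip_x): +1 when the subject faces image-right,
#' -1 when facing image-left. An exact tie (below the resolution epsilon,
#' 1e-6 trunk lengths) raises an undetermined-facing error.
#'
#' @param frame A `landmark_frame`.
#' @return +1 or -1.
#' @export
facing_direction <- function(frame) {
  eps <- 1e-6 * trunk_length_px(frame)
  dx <- frame["nose", "x"] - mid_hip(frame)[1]
  if (abs(dx) <= eps)
    stop("undetermined facing: nose is directly above the mid-hip",
         call. = FALSE)
  if (dx > 0) 1 else -1
}

#' Identify the front leg
#'
#' The front leg is the one whose ankle is displaced farther along the
#' facing direction from the mid-hip (horizontal foot distance). A
#' displacement tie returns `"undetermined"` so that callers may fall back
#' to the symmetric (Kiba) branch.
#'
#' @param frame A `landmark_frame`.
#' @param facing Optional facing override (+1/-1); computed if `NULL`.
#' @return `"left"`, `"right"`, or `"undetermined"`.
#' @export
front_leg <- function(frame, facing = NULL) {
  if (is.null(facing)) facing <- facing_direction(frame)
  eps <- 1e-6 * trunk_length_px(frame)
  mh <- mid_hip(frame)[1]
  dl <- facing * (frame["left_ankle", "x"] - mh)
  dr <- facing * (frame["right_ankle", "x"] - mh)
  if (abs(dl - dr) <= eps) return("undetermined")
  if (dl > dr) "left" else "right"
}

#' Horizontal foot separation in trunk lengths
#'
#' `|ankle_left_x - ankle_right_x|` divided by trunk length, making the
#' measure invariant to subject size and camera distance.
#'
#' @param frame A `landmark_frame`.
#' @return Non-negative separation (trunk lengths).
#' @export
foot_separation <- function(frame) {
  tl <- trunk_length_px(frame)
  if (tl == 0)
    stop("degenerate geometry: zero trunk length", call. = FALSE)
  abs(frame["left_ankle", "x"] - frame["right_ankle", "x"]) / tl
}

#' Posterior weight-shift proxy
#'
#' Extends the torso axis (mid-shoulder through mid-hip) to the ground line
#' `y = max(ankle_y)` and expresses the intersection as a fraction of the
#' way from the front-foot x (0) to the back-foot x (1). A qualitative
#' indicator of forward-versus-backward bias, not a force measurement. The
#' value is clipped to \[0, 1\]; `out_of_base` records whether the unclipped
#' intersection fell outside the base of support.
#'
#' @param frame A `landmark_frame`.
#' @param front Which leg is in front (`"left"`/`"right"`); computed from
#'   the frame when `NULL`.
#' @return List with `w_back` (proportion) and `out_of_base` (flag).
#' @export
weight_shift_back <- function(frame, front = NULL) {
  ms <- mid_shoulder(frame); mh <- mid_hip(frame)
  tl <- vnorm(ms - mh)
  if (tl == 0) stop("degenerate geometry: zero trunk length", call. = FALSE)
  eps <- 1e-6 * tl
  if (abs(mh[2] - ms[2]) <= eps)
    stop("degenerate geometry: trunk axis horizontal", call. = FALSE)
  if (is.null(front)) front <- front_leg(frame)
  if (front == "undetermined")
    stop("front leg undetermined: cannot orient the base of support",
         call. = FALSE)
  ground_y <- max(frame["left_ankle", "y"], frame["right_ankle", "y"])
  x_int <- ms[1] + (mh[1] - ms[1]) * (ground_y - ms[2]) / (mh[2] - ms[2])
  x_front <- frame[paste0(front, "_ankle"), "x"]
  x_back <- frame[paste0(setdiff(c("left", "right"), front), "_ankle"), "x"]
  if (abs(x_back - x_front) <= eps)
    stop("degenerate geometry: feet coincident", call. = FALSE)
  w <- (x_int - x_front) / (x_back - x_front)
  list(w_back = min(1, max(0, w)), out_of_base = (w < 0 || w > 1))
}

#' Invisible-big-toe line check
#'
#' The forward-stance coaching cue that the front knee should hide the big
#' toe from the practitioner's own line of sight. Operationalised as a
#' lateral-view geometric check: the ray from the front-side eye through the
#' front knee is extended to the toe's vertical level; the toe is hidden
#' when the ray reaches or passes the toe along the facing direction.
#'
#' @param frame A `landmark_frame`.
#' @param front Front leg (`"left"`/`"right"`); computed when `NULL`.
#' @param facing Facing direction; computed when `NULL`.
#' @return Logical `toe_hidden` flag.
#' @export
toe_visibility <- function(frame, front = NULL, facing = NULL) {
  if (is.null(facing)) facing <- facing_direction(frame)
  if (is.null(front)) front <- front_leg(frame, facing)
  if (front == "undetermined")
    stop("front leg undetermined: toe check needs a front leg", call. = FALSE)
  eye <- frame[paste0(front, "_eye"), ]
  knee <- frame[paste0(front, "_knee"), ]
  toe <- frame[paste0(front, "_foot_index"), ]
  if (knee["y"] == eye["y"])
    stop("degenerate geometry: eye and knee at equal height", call. = FALSE)
  if (eye["y"] >= knee["y"])
    stop("degenerate geometry: eye must be above the knee", call. = FALSE)
  x_ray <- eye["x"] + (knee["x"] - eye["x"]) *
    (toe["y"] - eye["y"]) / (knee["y"] - eye["y"])
  unname(facing * (x_ray - toe["x"]) >= 0)
}

knee_inter_angle <- function(frame, side) {
  joint_angle(frame[paste0(side, "_hip"), 1:2],
              frame[paste0(side, "_knee"), 1:2],
              frame[paste0(side, "_ankle"), 1:2])
}

elbow_inter_angle <- function(frame, side) {
  joint_angle(frame[paste0(side, "_shoulder"), 1:2],
              frame[paste0(side, "_elbow"), 1:2],
              frame[paste0(side, "_wrist"), 1:2])
}

# joints that must pass the confidence gate before any stance feature is used
CORE_JOINTS <- c("nose", "left_shoulder", "right_shoulder",
                 "left_hip", "right_hip", "left_knee", "right_knee",
                 "left_ankle", "right_ankle")

#' Extract the full per-frame feature set
#'
#' Computes every kinematic feature used by the stance rules and exercise
#' logic. When the confidence gate fails on the core joints the frame is
#' marked unreliable and the dependent fields are `NA`; no error is raised.
#'
#' @param frame A `landmark_frame`.
#' @param min_conf Confidence gate applied to the core joints (default 0.5).
#' @return A `kinematic_features` list: `F_left`, `F_right` (knee flexion,
#'   deg), `F_front`, `F_back`, `elbow_angle_left`, `elbow_angle_right`
#'   (inter-joint, deg), `theta_body` (deg from vertical, unsigned),
#'   `lean_forward` (+1 forward / -1 backward / 0), `shin_left`,
#'   `shin_right` (deg from vertical), `D_feet` (trunk lengths), `W_back`,
#'   `w_out_of_base`, `facing`, `front_leg`, `toe_hidden`, `reliable`, `t_s`.
#' @export
extract_features <- function(frame, min_conf = 0.5) {
  stopifnot(inherits(frame, "landmark_frame"))
  out <- list(F_left = NA_real_, F_right = NA_real_,
              F_front = NA_real_, F_back = NA_real_,
              elbow_angle_left = NA_real_, elbow_angle_right = NA_real_,
              theta_body = NA_real_, lean_forward = NA_real_,
              shin_left = NA_real_, shin_right = NA_real_,
              D_feet = NA_real_, W_back = NA_real_, w_out_of_base = NA,
              facing = NA_real_, front_leg = "undetermined",
              toe_hidden = NA, reliable = FALSE, t_s = frame_time(frame))
  if (!frame_is_reliable(frame, CORE_JOINTS, min_conf)) {
    class(out) <- "kinematic_features"
    return(out)
  }
  out$reliable <- TRUE
  out$F_left <- flexion(knee_inter_angle(frame, "left"))
  out$F_right <- flexion(knee_inter_angle(frame, "right"))
  out$shin_left <- segment_inclination(frame["left_knee", 1:2],
                                       frame["left_ankle", 1:2])
  out$shin_right <- segment_inclination(frame["right_knee", 1:2],
                                        frame["right_ankle", 1:2])
  out$theta_body <- trunk_inclination(frame)
  out$D_feet <- foot_separation(frame)
  facing <- tryCatch(facing_direction(frame), error = function(e) NA_real_)
  out$facing <- facing
  if (!is.na(facing)) {
    ms <- mid_shoulder(frame); mh <- mid_hip(frame)
    dx <- (ms[1] - mh[1]) * facing
    eps <- 1e-6 * trunk_length_px(frame)
    out$lean_forward <- if (abs(dx) <= eps) 0 else sign(dx)
    fl <- front_leg(frame, facing)
    out$front_leg <- fl
    if (fl != "undetermined") {
      out$F_front <- if (fl == "left") out$F_left else out$F_right
      out$F_back <- if (fl == "left") out$F_right else out$F_left
      ws <- tryCatch(weight_shift_back(frame, front = fl),
                     error = function(e) NULL)
      if (!is.null(ws)) {
        out$W_back <- ws$w_back
        out$w_out_of_base <- ws$out_of_base
      }
      eye_ok <- frame_is_reliable(frame,
                                  c(paste0(fl, "_eye"),
                                    paste0(fl, "_foot_index")), min_conf)
      if (eye_ok)
        out$toe_hidden <- tryCatch(toe_visibility(frame, fl, facing),
                                   error = function(e) NA)
    }
  }
  if (frame_is_reliable(frame, c("left_elbow", "left_wrist"), min_conf))
    out$elbow_angle_left <- elbow_inter_angle(frame, "left")
  if (frame_is_reliable(frame, c("right_elbow", "right_wrist"), min_conf))
    out$elbow_angle_right <- elbow_inter_angle(frame, "right")
  class(out) <- "kinematic_features"
  out
}

#' @export
print.kinematic_features <- function(x, ...) {
  cat(sprintf(paste0("<kinematic_features> t=%.3fs reliable=%s\n",
                     "  knee flexion L/R: %.1f / %.1f deg  trunk: %.1f deg\n",
                     "  D_feet: %.2f TL  W_back: %s  front leg: %s\n"),
              x$t_s, x$reliable, x$F_left, x$F_right, x$theta_body,
              x$D_feet, ifelse(is.na(x$W_back), "NA",
                               sprintf("%.2f", x$W_back)), x$front_leg))
  invisible(x)
}

#' Per-frame feature table for a sequence
#'
#' @param seq A `landmark_sequence`.
#' @param min_conf Confidence gate (default 0.5).
#' @return A data.frame with one row per frame and one column per
#'   `kinematic_features` field.
#' @export
feature_table <- function(seq, min_conf = 0.5) {
  stopifnot(inherits(seq, "landmark_sequence"))
  rows <- lapply(seq$frames, function(fr) {
    f <- extract_features(fr, min_conf)
    as.data.frame(unclass(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a per-frame feature table as CSV
#'
#' @param seq A `landmark_sequence`.
#' @param path Output CSV path.
#' @param min_conf Confidence gate.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(seq, path, min_conf = 0.5) {
  utils::write.csv(feature_table(seq, min_conf), path, row.names = FALSE)
  invisible(path)
}
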