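#' @title Repetition counting with hysteresis
#' @description Squat and push-up repetitions are counted by a
#'   Top -> Bottom -> Top finite-state machine over an inter-joint angle
#'   signal (knee angle for squats, elbow angle for push-ups), with a
#'   hysteresis dead band between the two thresholds, a dwell requirement
#'   to enter each state, and a refractory lockout after each counted
#'   repetition, preventing chatter from landmark jitter or mid-exercise
#'   pauses.
#' @name exercise
NULL

#' Repetition-counter configuration
#'
#' Thresholds are expressed in the raw inter-joint angle convention (180 =
#' fully extended): the Top state holds at or above `theta_top_deg`, the
#' Bottom state at or below `theta_bottom_deg`; the gap between them is the
#' hysteresis dead band.
#'
#' @param exercise `"squat"` or `"pushup"`.
#' @param theta_top_deg Top-state threshold in degrees. Defaults: squat 160,
#'   push-up 150.
#' @param theta_bottom_deg Bottom-state threshold in degrees (must be below
#'   `theta_top_deg`). Defaults: squat 100, push-up 90.
#' @param aggregate How the left/right joint pair is combined: `"min"`
#'   (conservative, the default) or `"mean"`.
#' @param min_dwell_frames Consecutive frames required to enter a state;
#'   default 2.
#' @param refractory_s Lockout after a counted repetition (seconds);
#'   default 0.3.
#' @param T_plank_deg Push-up plank tolerance: frames whose
#'   shoulder-hip-ankle angle falls below `180 - T_plank_deg` are gated
#'   out; default 20.
#' @return A `rep_config` list.
#' @export
rep_config <- function(exercise = c("squat", "pushup"),
                       theta_top_deg = NULL, theta_bottom_deg = NULL,
                       aggregate = c("min", "mean"),
                       min_dwell_frames = 2L, refractory_s = 0.3,
                       T_plank_deg = 20) {
  exercise <- match.arg(exercise)
  aggregate <- match.arg(aggregate)
  if (is.null(theta_top_deg))
    theta_top_deg <- if (exercise == "squat") 160 else 150
  if (is.null(theta_bottom_deg))
    theta_bottom_deg <- if (exercise == "squat") 100 else 90
  if (theta_bottom_deg >= theta_top_deg)
    stop("config error: theta_bottom_deg must be below theta_top_deg ",
         "(the gap is the hysteresis dead band)", call. = FALSE)
  if (min_dwell_frames < 1L || refractory_s < 0)
    stop("config error: min_dwell_frames >= 1 and refractory_s >= 0",
         call. = FALSE)
  structure(list(exercise = exercise, theta_top_deg = theta_top_deg,
                 theta_bottom_deg = theta_bottom_deg, aggregate = aggregate,
                 min_dwell_frames = as.integer(min_dwell_frames),
                 refractory_s = refractory_s, T_plank_deg = T_plank_deg),
            class = "rep_config")
}

#' Per-frame exercise angle signal with reliability gate
#'
#' Squats track the knee inter-joint angle (hip-knee-ankle); push-ups the
#' elbow angle (shoulder-elbow-wrist). Left and right are combined by the
#' configured aggregate. Push-up frames additionally require the
#' shoulder-hip-ankle angle to stay within the plank tolerance.
#'
#' @param seq A `landmark_sequence`.
#' @param cfg A [rep_config()].
#' @param min_conf Confidence gate on the involved joints.
#' @return Data.frame with columns `t_s`, `angle_deg`, `gate`.
#' @export
exercise_signal <- function(seq, cfg, min_conf = 0.5) {
  stopifnot(inherits(seq, "landmark_sequence"), inherits(cfg, "rep_config"))
  joints <- if (cfg$exercise == "squat")
    c("left_hip", "left_knee", "left_ankle",
      "right_hip", "right_knee", "right_ankle")
  else
    c("left_shoulder", "left_elbow", "left_wrist",
      "right_shoulder", "right_elbow", "right_wrist")
  plank_joints <- c("left_shoulder", "right_shoulder", "left_hip",
                    "right_hip", "left_ankle", "right_ankle")
  rows <- lapply(seq$frames, function(fr) {
    gate <- frame_is_reliable(fr, joints, min_conf)
    ang <- NA_real_
    if (gate) {
      lr <- if (cfg$exercise == "squat")
        c(knee_inter_angle(fr, "left"), knee_inter_angle(fr, "right"))
      else
        c(elbow_inter_angle(fr, "left"), elbow_inter_angle(fr, "right"))
      ang <- if (cfg$aggregate == "min") min(lr) else mean(lr)
      if (cfg$exercise == "pushup") {
        if (!frame_is_reliable(fr, plank_joints, min_conf)) {
          gate <- FALSE
        } else {
          plank <- joint_angle(mid_shoulder(fr), mid_hip(fr),
                               midpoint2(fr["left_ankle", ],
                                         fr["right_ankle", ]))
          if (plank < 180 - cfg$T_plank_deg) gate <- FALSE
        }
      }
    }
    data.frame(t_s = frame_time(fr), angle_deg = ang, gate = gate)
  })
  do.call(rbind, rows)
}

#' Count repetitions in an angle signal
#'
#' State machine over gated frames only: Top is entered after
#' `min_dwell_frames` consecutive gated frames at or above `theta_top_deg`;
#' from Top, Bottom is entered after the dwell at or below
#' `theta_bottom_deg`; a repetition is counted on the return to Top, after
#' which Bottom entries are ignored for `refractory_s` seconds. Frames with
#' `gate = FALSE` do not advance the machine.
#'
#' @param signal Data.frame with `t_s`, `angle_deg`, `gate` columns (as from
#'   [exercise_signal()]), times increasing.
#' @param cfg A [rep_config()].
#' @return A `rep_count` list: `count` and `events`, a data.frame with one
#'   row per repetition (`t_top_enter`, `t_bottom`, `t_complete` seconds).
#' @export
count_reps <- function(signal, cfg) {
  stopifnot(inherits(cfg, "rep_config"))
  if (cfg$theta_bottom_deg >= cfg$theta_top_deg)
    stop("config error: theta_bottom_deg must be below theta_top_deg",
         call. = FALSE)
  keep <- signal$gate & !is.na(signal$angle_deg)
  t <- signal$t_s[keep]; a <- signal$angle_deg[keep]
  dwell <- cfg$min_dwell_frames
  state <- "idle"          # idle -> top -> bottom -> top (count)
  run_top <- 0L; run_bot <- 0L
  t_top_enter <- NA_real_; t_bottom <- NA_real_
  refractory_until <- -Inf
  events <- list()
  for (i in seq_along(a)) {
    is_top <- a[i] >= cfg$theta_top_deg
    is_bot <- a[i] <= cfg$theta_bottom_deg
    run_top <- if (is_top) run_top + 1L else 0L
    run_bot <- if (is_bot) run_bot + 1L else 0L
    if (state %in% c("idle", "bottom") && run_top >= dwell) {
      if (state == "bottom") {
        events[[length(events) + 1L]] <-
          data.frame(t_top_enter = t_top_enter, t_bottom = t_bottom,
                     t_complete = t[i])
        refractory_until <- t[i] + cfg$refractory_s
      }
      state <- "top"
      t_top_enter <- t[i - dwell + 1L]
    } else if (state == "top" && run_bot >= dwell &&
               t[i - dwell + 1L] > refractory_until) {
      state <- "bottom"
      t_bottom <- t[i - dwell + 1L]
    }
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(t_top_enter = numeric(0), t_bottom = numeric(0),
                            t_complete = numeric(0))
  structure(list(count = nrow(events), events = events, config = cfg),
            class = "rep_count")
}

#' @export
print.rep_count <- function(x, ...) {
  cat(sprintf("<rep_count> %d %s repetition(s)\n", x$count,
              x$config$exercise))
  if (x$count > 0) print(round(x$events, 3))
  invisible(x)
}

#' Rep-level precision and recall against reference events
#'
#' Greedy chronological one-to-one matching of detected completion times to
#' reference times within a temporal tolerance window. Conventions for
#' empty sets: precision is 1 when there are no detections, recall is 1
#' when there are no references.
#'
#' @param detected Numeric vector of detected completion times (seconds),
#'   or a `rep_count` object.
#' @param reference Numeric vector of reference repetition times (seconds).
#' @param tolerance_s Matching half-window in seconds (>= 0); default 0.5.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, and the
#'   matched index pairs.
#' @export
evaluate_reps <- function(detected, reference, tolerance_s = 0.5) {
  if (inherits(detected, "rep_count")) detected <- detected$events$t_complete
  if (tolerance_s < 0) stop("tolerance_s must be >= 0", call. = FALSE)
  detected <- sort(as.numeric(detected))
  reference <- sort(as.numeric(reference))
  used_ref <- rep(FALSE, length(reference))
  matches <- list()
  for (i in seq_along(detected)) {
    cand <- which(!used_ref & abs(reference - detected[i]) <= tolerance_s)
    if (length(cand)) {
      j <- cand[which.min(abs(reference[cand] - detected[i]))]
      used_ref[j] <- TRUE
      matches[[length(matches) + 1L]] <- c(det = i, ref = j)
    }
  }
  tp <- length(matches)
  fp <- length(detected) - tp
  fn <- length(reference) - tp
  precision <- if (length(detected) == 0L) 1 else tp / (tp + fp)
  recall <- if (length(reference) == 0L) 1 else tp / (tp + fn)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       matches = if (tp) do.call(rbind, matches)
                 else matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("det", "ref"))))
}
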