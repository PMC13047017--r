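#' @title Synthetic skeleton simulator
#' @description A forward-kinematics generator of 33-landmark sequences with
#'   ground-truth manifests, emulating a single subject viewed laterally by
#'   a fixed, level camera: static stance holds, squat and push-up cycles,
#'   and punch events. The planar kinematic chain is posed to exactly the
#'   requested joint angles, so at zero noise every specified angle is
#'   recoverable by the kinematics module to numerical precision; Gaussian
#'   landmark jitter, confidence dropout, and optional left/right keypoint
#'   swaps emulate the dominant failure modes of single-camera pose
#'   estimators.
#' @name synthetic
NULL

#' Skeleton geometry parameters
#'
#' Segment lengths are fractions of body height; defaults are standard
#' anthropometric approximations.
#'
#' @param body_height_px Body height in pixels; default 500.
#' @param trunk,thigh,shank,upper_arm,forearm Segment fractions of body
#'   height; defaults 0.30, 0.25, 0.25, 0.17, 0.15.
#' @param facing +1 (facing image-right) or -1; default +1.
#' @param anchor Mid-hip image position (pixels, c(x, y)); default
#'   c(320, 300).
#' @return A `skeleton_params` list (with derived pixel lengths).
#' @export
skeleton_params <- function(body_height_px = 500, trunk = 0.30, thigh = 0.25,
                            shank = 0.25, upper_arm = 0.17, forearm = 0.15,
                            facing = 1, anchor = c(320, 300)) {
  stopifnot(body_height_px > 0, trunk > 0, thigh > 0, shank > 0,
            upper_arm > 0, forearm > 0, facing %in% c(-1, 1))
  structure(list(H = body_height_px,
                 trunk_px = trunk * body_height_px,
                 thigh_px = thigh * body_height_px,
                 shank_px = shank * body_height_px,
                 upper_arm_px = upper_arm * body_height_px,
                 forearm_px = forearm * body_height_px,
                 facing = facing, anchor = as.numeric(anchor)),
            class = "skeleton_params")
}

#' Landmark noise model
#'
#' @param jitter_sd_px Gaussian per-coordinate landmark noise SD (pixels);
#'   default 0.
#' @param dropout_prob Per-landmark per-frame probability of low-confidence
#'   dropout; default 0.
#' @param dropped_conf Confidence assigned on dropout; default 0.1.
#' @param swap_prob Per-frame probability of a left/right keypoint swap
#'   event (a known failure mode of pose estimators); default 0.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return A `noise_model` list.
#' @export
noise_model <- function(jitter_sd_px = 0, dropout_prob = 0,
                        dropped_conf = 0.1, swap_prob = 0, seed = NULL) {
  stopifnot(jitter_sd_px >= 0, dropout_prob >= 0, dropout_prob <= 1,
            dropped_conf >= 0, dropped_conf <= 1,
            swap_prob >= 0, swap_prob <= 1)
  structure(list(jitter_sd_px = jitter_sd_px, dropout_prob = dropout_prob,
                 dropped_conf = dropped_conf, swap_prob = swap_prob,
                 seed = seed),
            class = "noise_model")
}

with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# solve the thigh angle (from image-down) so the ankle lands at horizontal
# offset dx from the hip while the knee flexion equals F_deg
solve_leg <- function(dx, F_deg, thigh, shank, bend_sign) {
  Fr <- F_deg * pi / 180
  g <- function(phi) thigh * sin(phi) + shank * sin(phi + bend_sign * Fr) - dx
  lo <- -80 * pi / 180; hi <- 80 * pi / 180
  if (g(lo) * g(hi) > 0)
    stop("generation error: impossible leg geometry (flexion ", F_deg,
         " deg, ankle offset ", round(dx, 1), " px)", call. = FALSE)
  phi <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(knee = c(thigh * sin(phi), thigh * cos(phi)),
       ankle = c(thigh * sin(phi) + shank * sin(phi + bend_sign * Fr),
                 thigh * cos(phi) + shank * cos(phi + bend_sign * Fr)))
}

# place the arm chain: upper-arm direction angle alpha from image-down,
# elbow inter-joint angle theta_deg
arm_chain <- function(shoulder, alpha_deg, theta_deg, ua, fa, bend_sign) {
  a <- alpha_deg * pi / 180
  b <- a + bend_sign * (180 - theta_deg) * pi / 180
  elbow <- shoulder + ua * c(sin(a), cos(a))
  wrist <- elbow + fa * c(sin(b), cos(b))
  list(elbow = elbow, wrist = wrist)
}

# assemble a 33-point frame from the main joint positions; remaining face,
# hand and foot landmarks are placed at fixed plausible offsets
build_frame <- function(joints, t_s, skel) {
  f <- skel$facing; H <- skel$H
  nm <- landmark_names()
  pts <- matrix(0, nrow = N_LANDMARKS, ncol = 4,
                dimnames = list(nm, c("x", "y", "z", "conf")))
  pts[, "conf"] <- 1
  set_pt <- function(name, p) pts[name, c("x", "y")] <<- p
  head_c <- joints$mid_shoulder + c(0.04 * H * f, -0.12 * H)
  set_pt("nose", head_c + c(0.05 * H * f, 0))
  for (s in c("left", "right")) {
    set_pt(paste0(s, "_eye"), head_c + c(0.035 * H * f, -0.02 * H))
    set_pt(paste0(s, "_eye_inner"), head_c + c(0.030 * H * f, -0.02 * H))
    set_pt(paste0(s, "_eye_outer"), head_c + c(0.040 * H * f, -0.02 * H))
    set_pt(paste0(s, "_ear"), head_c + c(-0.01 * H * f, -0.01 * H))
    set_pt(paste0("mouth_", s), head_c + c(0.045 * H * f, 0.015 * H))
  }
  for (s in c("left", "right")) {
    set_pt(paste0(s, "_shoulder"), joints$mid_shoulder)
    set_pt(paste0(s, "_hip"), joints$mid_hip)
    set_pt(paste0(s, "_elbow"), joints[[paste0(s, "_elbow")]])
    set_pt(paste0(s, "_wrist"), joints[[paste0(s, "_wrist")]])
    set_pt(paste0(s, "_knee"), joints[[paste0(s, "_knee")]])
    set_pt(paste0(s, "_ankle"), joints[[paste0(s, "_ankle")]])
    w <- joints[[paste0(s, "_wrist")]]
    set_pt(paste0(s, "_pinky"), w + c(0.02 * H * f, 0.01 * H))
    set_pt(paste0(s, "_index"), w + c(0.025 * H * f, 0.005 * H))
    set_pt(paste0(s, "_thumb"), w + c(0.015 * H * f, 0))
    a <- joints[[paste0(s, "_ankle")]]
    set_pt(paste0(s, "_heel"), a + c(-0.05 * H * f, 0.02 * H))
    set_pt(paste0(s, "_foot_index"), a + c(0.10 * H * f, 0.02 * H))
  }
  landmark_frame(pts, t_s = t_s)
}

PAIRED_LANDMARKS <- c("eye_inner", "eye", "eye_outer", "ear", "shoulder",
                      "elbow", "wrist", "pinky", "index", "thumb", "hip",
                      "knee", "ankle", "heel", "foot_index")

apply_noise_frame <- function(frame, noise) {
  pts <- unclass(frame)
  t_s <- attr(frame, "t_s")
  if (noise$swap_prob > 0 && stats::runif(1) < noise$swap_prob) {
    for (p in PAIRED_LANDMARKS) {
      l <- paste0("left_", p); r <- paste0("right_", p)
      tmp <- pts[l, ]; pts[l, ] <- pts[r, ]; pts[r, ] <- tmp
    }
  }
  if (noise$jitter_sd_px > 0) {
    pts[, "x"] <- pts[, "x"] + stats::rnorm(N_LANDMARKS, 0, noise$jitter_sd_px)
    pts[, "y"] <- pts[, "y"] + stats::rnorm(N_LANDMARKS, 0, noise$jitter_sd_px)
  }
  if (noise$dropout_prob > 0) {
    drop <- stats::runif(N_LANDMARKS) < noise$dropout_prob
    pts[drop, "conf"] <- noise$dropped_conf
  }
  landmark_frame(pts, t_s = t_s)
}

#' Preset stance scenarios at the centres of the rule regions
#'
#' Convenience specifications of the three stances placed well inside the
#' default decision regions: a deep front-knee bend with symmetric base for
#' Zenkutsu, a deep rear-knee bend with posterior weight placement for
#' Kokutsu, and a wide symmetric bend for Kiba.
#'
#' @param stance `"zenkutsu"`, `"kokutsu"`, or `"kiba"`.
#' @return List with `spec` (a stance specification for
#'   [simulate_stance()]) and the true `label`.
#' @export
stance_preset <- function(stance = c("zenkutsu", "kokutsu", "kiba")) {
  stance <- match.arg(stance)
  spec <- switch(stance,
    zenkutsu = list(F_left = 60, F_right = 10, stance_width = 1.4,
                    trunk_tilt = 0, front_leg = "left", hip_bias = 0.5),
    kokutsu = list(F_left = 10, F_right = 60, stance_width = 1.2,
                   trunk_tilt = 0, front_leg = "left", hip_bias = 0.75),
    kiba = list(F_left = 60, F_right = 60, stance_width = 1.8,
                trunk_tilt = 0, front_leg = "none", hip_bias = 0.5))
  list(spec = spec, label = stance)
}

stance_joint_layout <- function(spec, skel) {
  f <- skel$facing
  tl <- skel$trunk_px
  w_px <- spec$stance_width * tl
  hb <- if (is.null(spec$hip_bias)) 0.5 else spec$hip_bias
  mh <- skel$anchor
  tilt <- spec$trunk_tilt * pi / 180
  ms <- mh + tl * c(sin(tilt) * f, -cos(tilt))
  front <- if (is.null(spec$front_leg)) "none" else spec$front_leg
  if (front == "none") {
    dx <- c(left = -w_px / 2, right = w_px / 2)
  } else {
    back <- setdiff(c("left", "right"), front)
    dx <- c(0, 0); names(dx) <- c(front, back)
    dx[front] <- f * hb * w_px
    dx[back] <- -f * (1 - hb) * w_px
  }
  joints <- list(mid_hip = mh, mid_shoulder = ms)
  for (s in c("left", "right")) {
    bend <- if (dx[s] != 0) sign(dx[s]) else f
    leg <- solve_leg(dx[[s]], spec[[paste0("F_", s)]],
                     skel$thigh_px, skel$shank_px, bend)
    joints[[paste0(s, "_knee")]] <- mh + leg$knee
    joints[[paste0(s, "_ankle")]] <- mh + leg$ankle
  }
  for (s in c("left", "right")) {
    arm <- arm_chain(ms, alpha_deg = 15 * f, theta_deg = 150,
                     ua = skel$upper_arm_px, fa = skel$forearm_px,
                     bend_sign = f)
    joints[[paste0(s, "_elbow")]] <- arm$elbow
    joints[[paste0(s, "_wrist")]] <- arm$wrist
  }
  joints
}

#' Simulate a static stance hold
#'
#' @param spec Stance specification: `F_left`, `F_right` (knee flexion,
#'   deg), `stance_width` (trunk lengths), `trunk_tilt` (deg, positive
#'   leans toward the facing direction), `front_leg` (`"left"`, `"right"`,
#'   or `"none"` for a symmetric base), optional `hip_bias` (fraction of
#'   the base of support, front = 0, under the mid-hip; default 0.5).
#'   See [stance_preset()].
#' @param n_frames Number of frames.
#' @param fps Frame rate in Hz; default 30.
#' @param skel A [skeleton_params()].
#' @param noise A [noise_model()].
#' @return List with `seq` (a `landmark_sequence`) and `truth` (per-frame
#'   true angles and the scenario parameters).
#' @export
simulate_stance <- function(spec, n_frames = 30L, fps = 30,
                            skel = skeleton_params(),
                            noise = noise_model()) {
  joints <- stance_joint_layout(spec, skel)
  t <- (seq_len(n_frames) - 1L) / fps
  with_sim_seed(noise$seed, {
    frames <- lapply(t, function(ti)
      apply_noise_frame(build_frame(joints, ti, skel), noise))
    truth <- list(kind = "stance",
                  per_frame = data.frame(t_s = t,
                                         F_left = spec$F_left,
                                         F_right = spec$F_right,
                                         theta_body = abs(spec$trunk_tilt),
                                         D_feet = spec$stance_width),
                  spec = spec)
    list(seq = landmark_sequence(frames, fps_nominal = fps), truth = truth)
  })
}

# chord distance hip -> ankle for a flexion F with equal thigh/shank lengths
leg_chord <- function(F_deg, thigh, shank) {
  a <- (180 - F_deg) * pi / 180
  sqrt(thigh^2 + shank^2 - 2 * thigh * shank * cos(pi - a))
}

standing_layout <- function(F_deg, skel, ground_y) {
  f <- skel$facing
  mh <- c(skel$anchor[1], ground_y - leg_chord(F_deg, skel$thigh_px,
                                               skel$shank_px))
  ms <- mh + skel$trunk_px * c(0, -1)
  joints <- list(mid_hip = mh, mid_shoulder = ms)
  for (s in c("left", "right")) {
    leg <- solve_leg(0, F_deg, skel$thigh_px, skel$shank_px, f)
    joints[[paste0(s, "_knee")]] <- mh + leg$knee
    joints[[paste0(s, "_ankle")]] <- mh + leg$ankle
  }
  for (s in c("left", "right")) {
    arm <- arm_chain(ms, alpha_deg = 70 * f, theta_deg = 165,
                     ua = skel$upper_arm_px, fa = skel$forearm_px,
                     bend_sign = f)
    joints[[paste0(s, "_elbow")]] <- arm$elbow
    joints[[paste0(s, "_wrist")]] <- arm$wrist
  }
  joints
}

#' Simulate a squat bout
#'
#' The knee inter-joint angle follows a raised-cosine trajectory between
#' `theta_top_true` and `theta_bottom_true`, starting and ending at the
#' top, with the feet planted on a fixed ground line and the hips
#' descending accordingly. The truth manifest lists the completion time of
#' each repetition (the return to the top of each cycle).
#'
#' @param n_reps Number of repetitions (>= 0).
#' @param theta_top_true,theta_bottom_true True knee-angle extremes in
#'   degrees; defaults 175 and 70 (a deep squat).
#' @param period_s Seconds per repetition cycle; default 2.
#' @param fps Frame rate (Hz); default 30.
#' @param skel A [skeleton_params()].
#' @param noise A [noise_model()].
#' @param lead_s,tail_s Hold time at the top before and after the bout
#'   (seconds); defaults 0.5.
#' @return List with `seq` and `truth` (`rep_times`, per-frame true knee
#'   angle).
#' @export
simulate_squat <- function(n_reps, theta_top_true = 175,
                           theta_bottom_true = 70, period_s = 2, fps = 30,
                           skel = skeleton_params(), noise = noise_model(),
                           lead_s = 0.5, tail_s = 0.5) {
  if (n_reps < 0) stop("n_reps must be >= 0", call. = FALSE)
  if (theta_bottom_true >= theta_top_true)
    stop("theta_bottom_true must be below theta_top_true", call. = FALSE)
  dur <- lead_s + n_reps * period_s + tail_s
  t <- seq(0, dur, by = 1 / fps)
  mid <- (theta_top_true + theta_bottom_true) / 2
  amp <- (theta_top_true - theta_bottom_true) / 2
  theta <- ifelse(t < lead_s | t > lead_s + n_reps * period_s,
                  theta_top_true,
                  mid + amp * cos(2 * pi * (t - lead_s) / period_s))
  ground_y <- skel$anchor[2] + leg_chord(0, skel$thigh_px, skel$shank_px)
  with_sim_seed(noise$seed, {
    frames <- lapply(seq_along(t), function(i) {
      joints <- standing_layout(180 - theta[i], skel, ground_y)
      apply_noise_frame(build_frame(joints, t[i], skel), noise)
    })
    truth <- list(kind = "squat",
                  rep_times = if (n_reps > 0) lead_s + period_s * seq_len(n_reps)
                              else numeric(0),
                  per_frame = data.frame(t_s = t, knee_angle_deg = theta))
    list(seq = landmark_sequence(frames, fps_nominal = fps), truth = truth)
  })
}

pushup_layout <- function(theta_elbow, skel, sag_px = 0) {
  f <- skel$facing
  ms <- skel$anchor   # shoulders at the anchor in the horizontal configuration
  mh <- ms + c(-f * skel$trunk_px, sag_px)
  joints <- list(mid_shoulder = ms, mid_hip = mh)
  leg_len <- skel$thigh_px + skel$shank_px
  ankle <- ms + c(-f * (skel$trunk_px + leg_len), 0)
  knee <- mh + (ankle - mh) * (skel$thigh_px / leg_len)
  for (s in c("left", "right")) {
    joints[[paste0(s, "_knee")]] <- knee
    joints[[paste0(s, "_ankle")]] <- ankle
  }
  for (s in c("left", "right")) {
    arm <- arm_chain(ms, alpha_deg = f * (180 - theta_elbow) / 2,
                     theta_deg = theta_elbow,
                     ua = skel$upper_arm_px, fa = skel$forearm_px,
                     bend_sign = -f)
    joints[[paste0(s, "_elbow")]] <- arm$elbow
    joints[[paste0(s, "_wrist")]] <- arm$wrist
  }
  joints
}

#' Simulate a push-up bout
#'
#' Horizontal-trunk configuration with the elbow angle cycling between the
#' two extremes. Optional plank-violation segments lower the hips so that
#' the shoulder-hip-ankle angle breaches the given sag, letting callers
#' verify that those frames are gated out.
#'
#' @param n_reps Number of repetitions (>= 0).
#' @param theta_top_true,theta_bottom_true True elbow-angle extremes in
#'   degrees; defaults 170 and 60.
#' @param period_s Seconds per cycle; default 2.
#' @param fps Frame rate (Hz); default 30.
#' @param skel A [skeleton_params()].
#' @param noise A [noise_model()].
#' @param sag_windows Optional data.frame with `t_start`, `t_end` columns:
#'   during these intervals the hips sag by `sag_deg`.
#' @param sag_deg Shoulder-hip-ankle deviation from straight during sag
#'   windows (degrees); default 30.
#' @param lead_s,tail_s Hold time at the top; defaults 0.5.
#' @return List with `seq` and `truth` (`rep_times`, per-frame elbow angle
#'   and expected plank gate).
#' @export
simulate_pushup <- function(n_reps, theta_top_true = 170,
                            theta_bottom_true = 60, period_s = 2, fps = 30,
                            skel = skeleton_params(), noise = noise_model(),
                            sag_windows = NULL, sag_deg = 30,
                            lead_s = 0.5, tail_s = 0.5) {
  if (n_reps < 0) stop("n_reps must be >= 0", call. = FALSE)
  if (theta_bottom_true >= theta_top_true)
    stop("theta_bottom_true must be below theta_top_true", call. = FALSE)
  dur <- lead_s + n_reps * period_s + tail_s
  t <- seq(0, dur, by = 1 / fps)
  mid <- (theta_top_true + theta_bottom_true) / 2
  amp <- (theta_top_true - theta_bottom_true) / 2
  theta <- ifelse(t < lead_s | t > lead_s + n_reps * period_s,
                  theta_top_true,
                  mid + amp * cos(2 * pi * (t - lead_s) / period_s))
  in_sag <- rep(FALSE, length(t))
  if (!is.null(sag_windows) && nrow(sag_windows) > 0) {
    for (i in seq_len(nrow(sag_windows)))
      in_sag <- in_sag | (t >= sag_windows$t_start[i] &
                          t <= sag_windows$t_end[i])
  }
  # hip drop producing the requested shoulder-hip-ankle deviation
  a <- skel$trunk_px
  b <- skel$thigh_px + skel$shank_px
  sag_px <- if (any(in_sag)) {
    dev <- sag_deg * pi / 180
    stats::uniroot(function(h) atan(h / a) + atan(h / b) - dev,
                   c(0, a))$root
  } else 0
  with_sim_seed(noise$seed, {
    frames <- lapply(seq_along(t), function(i) {
      joints <- pushup_layout(theta[i], skel,
                              sag_px = if (in_sag[i]) sag_px else 0)
      apply_noise_frame(build_frame(joints, t[i], skel), noise)
    })
    truth <- list(kind = "pushup",
                  rep_times = if (n_reps > 0) lead_s + period_s * seq_len(n_reps)
                              else numeric(0),
                  per_frame = data.frame(t_s = t, elbow_angle_deg = theta,
                                         plank_ok = !in_sag))
    list(seq = landmark_sequence(frames, fps_nominal = fps), truth = truth)
  })
}

#' Simulate a punch (tsuki) after a stimulus
#'
#' The subject stands in guard; at `stimulus_t + true_latency_s` the wrists
#' drive forward along the facing direction by 1.2 trunk lengths within
#' 0.1 s, with the fast early acceleration characteristic of a straight
#' punch, then hold extended. `true_latency_s = Inf` produces a no-punch
#' (timeout) scenario.
#'
#' @param stimulus_t Stimulus time in seconds.
#' @param true_latency_s True reaction latency in seconds (> 0, or `Inf`).
#' @param fps Frame rate (Hz); default 30.
#' @param skel A [skeleton_params()].
#' @param noise A [noise_model()].
#' @param tail_s Recording time after the punch onset; default 0.8.
#' @return List with `seq` and `truth` (`stimulus_t`, `latency_s`,
#'   `punch_onset_t`).
#' @export
simulate_punch <- function(stimulus_t, true_latency_s, fps = 30,
                           skel = skeleton_params(), noise = noise_model(),
                           tail_s = 0.8) {
  if (!is.infinite(true_latency_s) && true_latency_s <= 0)
    stop("true_latency_s must be > 0", call. = FALSE)
  onset <- stimulus_t + true_latency_s
  dur <- if (is.infinite(onset)) stimulus_t + 2.5 else onset + tail_s
  t <- seq(0, dur, by = 1 / fps)
  if (stimulus_t <= min(t) || stimulus_t >= max(t))
    stop("stimulus outside the simulated span", call. = FALSE)
  f <- skel$facing
  reach <- 1.2 * skel$trunk_px
  with_sim_seed(noise$seed, {
    frames <- lapply(seq_along(t), function(i) {
      joints <- standing_layout(5, skel,
                                skel$anchor[2] +
                                  leg_chord(0, skel$thigh_px, skel$shank_px))
      # guard: wrists pulled in near the chest
      ms <- joints$mid_shoulder
      for (s in c("left", "right")) {
        joints[[paste0(s, "_elbow")]] <- ms + c(0.05 * f * skel$H, 0.10 * skel$H)
        joints[[paste0(s, "_wrist")]] <- ms + c(0.10 * f * skel$H, 0.05 * skel$H)
      }
      if (!is.infinite(onset) && t[i] > onset) {
        frac <- min(1, (t[i] - onset) / 0.1)^0.25
        adv <- c(f * reach * frac, 0)
        for (s in c("left", "right")) {
          joints[[paste0(s, "_wrist")]] <- joints[[paste0(s, "_wrist")]] + adv
          joints[[paste0(s, "_elbow")]] <- joints[[paste0(s, "_elbow")]] +
            adv * 0.5
        }
      }
      apply_noise_frame(build_frame(joints, t[i], skel), noise)
    })
    truth <- list(kind = "punch", stimulus_t = stimulus_t,
                  latency_s = true_latency_s, punch_onset_t = onset)
    list(seq = landmark_sequence(frames, fps_nominal = fps), truth = truth)
  })
}
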