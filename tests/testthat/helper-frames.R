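# Frame-construction helpers: a hand-laid upright pose facing image-right
# (independent of the package's forward-kinematics generator), with
# per-landmark coordinate and confidence overrides.

base_pose_coords <- function() {
  m <- rbind(
    nose = c(112, 28),
    left_eye_inner = c(110, 24), left_eye = c(110, 24),
    left_eye_outer = c(111, 24),
    right_eye_inner = c(110, 24), right_eye = c(110, 24),
    right_eye_outer = c(111, 24),
    left_ear = c(104, 26), right_ear = c(104, 26),
    mouth_left = c(112, 33), mouth_right = c(112, 33),
    left_shoulder = c(100, 50), right_shoulder = c(100, 50),
    left_elbow = c(105, 82), right_elbow = c(105, 82),
    left_wrist = c(110, 112), right_wrist = c(110, 112),
    left_pinky = c(112, 116), right_pinky = c(112, 116),
    left_index = c(113, 115), right_index = c(113, 115),
    left_thumb = c(111, 114), right_thumb = c(111, 114),
    left_hip = c(100, 110), right_hip = c(100, 110),
    left_knee = c(100, 160), right_knee = c(100, 160),
    left_ankle = c(100, 210), right_ankle = c(100, 210),
    left_heel = c(95, 214), right_heel = c(95, 214),
    left_foot_index = c(110, 214), right_foot_index = c(110, 214))
  m[landmark_names(), ]
}

make_test_frame <- function(overrides = list(), conf = 1, t_s = 0,
                            conf_overrides = list()) {
  nm <- landmark_names()
  pts <- matrix(0, nrow = 33, ncol = 4)
  pts[, 1:2] <- base_pose_coords()
  pts[, 4] <- conf
  for (n in names(overrides))
    pts[match(n, nm), 1:2] <- overrides[[n]]
  for (n in names(conf_overrides))
    pts[match(n, nm), 4] <- conf_overrides[[n]]
  landmark_frame(pts, t_s = t_s)
}

random_valid_sequence <- function(n_frames = 10, fps = 30) {
  frames <- lapply(seq_len(n_frames), function(i) {
    fr <- make_test_frame(t_s = (i - 1) / fps)
    pts <- unclass(fr)
    pts[, 1] <- pts[, 1] + stats::rnorm(33, 0, 3)
    pts[, 2] <- pts[, 2] + stats::rnorm(33, 0, 3)
    pts[, 3] <- stats::rnorm(33)
    pts[, 4] <- stats::runif(33)
    landmark_frame(pts, t_s = (i - 1) / fps)
  })
  landmark_sequence(frames, fps_nominal = fps)
}

expect_sequences_equal <- function(a, b, tol = 1e-9) {
  expect_equal(length(a), length(b))
  expect_equal(sequence_times(a), sequence_times(b), tolerance = tol)
  for (i in seq_len(length(a)))
    expect_equal(unclass(a$frames[[i]]), unclass(b$frames[[i]]),
                 tolerance = tol)
}

# minimal feature list accepted by classify_stance()
feat <- function(F_left = 0, F_right = 0, theta_body = 0, D_feet = 1,
                 W_back = 0.5, front_leg = "left", reliable = TRUE) {
  F_front <- if (front_leg == "left") F_left
             else if (front_leg == "right") F_right else NA_real_
  F_back <- if (front_leg == "left") F_right
            else if (front_leg == "right") F_left else NA_real_
  list(F_left = F_left, F_right = F_right, F_front = F_front,
       F_back = F_back, theta_body = theta_body, D_feet = D_feet,
       W_back = W_back, front_leg = front_leg, reliable = reliable)
}
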