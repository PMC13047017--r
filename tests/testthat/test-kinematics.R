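test_that("joint_angle matches hand cases and the law-of-cosines oracle", {
  expect_equal(joint_angle(c(0, 0), c(0, 1), c(0, 2)), 180)
  expect_equal(joint_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(joint_angle(c(2, 3), c(4, 7), c(9, 5)),
               loc_angle(c(2, 3), c(4, 7), c(9, 5)), tolerance = 1e-12)
  expect_error(joint_angle(c(1, 1), c(1, 1), c(0, 0)), "degenerate")
  set.seed(31)
  worst <- 0
  for (i in 1:2000) {
    p <- matrix(runif(6, -100, 100), 3, 2)
    if (all(p[2, ] == p[1, ]) || all(p[2, ] == p[3, ])) next
    worst <- max(worst, abs(joint_angle(p[1, ], p[2, ], p[3, ]) -
                            loc_angle(p[1, ], p[2, ], p[3, ])))
  }
  expect_lt(worst, 1e-9)  # absolute degrees
})

test_that("flexion is 180 minus the inter-joint angle with domain checks", {
  expect_equal(flexion(180), 0)
  expect_equal(flexion(90), 90)
  expect_equal(flexion(65), 115)
  expect_error(flexion(181))
  expect_error(flexion(-1))
})

test_that("segment_inclination agrees with an atan2 oracle", {
  expect_equal(segment_inclination(c(0, 0), c(0, 10)), 0)
  expect_equal(segment_inclination(c(0, 0), c(10, 10)), 45)
  expect_error(segment_inclination(c(1, 2), c(1, 2)), "degenerate")
  set.seed(32)
  for (i in 1:500) {
    p <- runif(2, -50, 50); q <- runif(2, -50, 50)
    if (all(p == q)) next
    v <- q - p
    expect_equal(segment_inclination(p, q),
                 atan2(abs(v[1]), v[2]) * 180 / pi, tolerance = 1e-9)
  }
})

test_that("trunk inclination reads 0 upright and 45 for a diagonal torso", {
  up <- make_test_frame()
  expect_equal(trunk_inclination(up), 0)
  tilted <- make_test_frame(overrides = list(
    left_shoulder = c(160, 50), right_shoulder = c(160, 50)))
  expect_equal(trunk_inclination(tilted), 45)
})

test_that("facing follows the nose and errors on an exact tie", {
  expect_equal(facing_direction(make_test_frame()), 1)
  left <- make_test_frame(overrides = list(nose = c(88, 28)))
  expect_equal(facing_direction(left), -1)
  tie <- make_test_frame(overrides = list(nose = c(100, 28)))
  expect_error(facing_direction(tie), "undetermined")
})

test_that("front leg is the ankle farther along the facing direction", {
  fr <- make_test_frame(overrides = list(left_ankle = c(300, 210),
                                         right_ankle = c(100, 210),
                                         left_hip = c(200, 110),
                                         right_hip = c(200, 110),
                                         left_shoulder = c(200, 50),
                                         right_shoulder = c(200, 50),
                                         nose = c(215, 28)))
  expect_equal(front_leg(fr), "left")
  expect_equal(front_leg(make_test_frame()), "undetermined")  # equal ankle x
})

test_that("foot separation is trunk-normalised and scale invariant", {
  fr <- make_test_frame(overrides = list(left_ankle = c(100, 210),
                                         right_ankle = c(160, 210)))
  expect_equal(foot_separation(fr), 1)  # 60 px over a 60 px trunk
  expect_equal(foot_separation(make_test_frame()), 0)
  doubled <- landmark_frame(cbind(unclass(fr)[, 1:2] * 2, unclass(fr)[, 3:4]))
  expect_equal(foot_separation(doubled), foot_separation(fr), tolerance = 1e-12)
})

test_that("weight-shift proxy matches symmetry cases and a line oracle", {
  mk <- function(shoulder_x) make_test_frame(overrides = list(
    left_shoulder = c(shoulder_x, 50), right_shoulder = c(shoulder_x, 50),
    nose = c(115, 28),
    left_ankle = c(160, 210), right_ankle = c(40, 210)))
  # vertical trunk midway between the feet (hips at x=100)
  ws <- weight_shift_back(mk(100))
  expect_equal(ws$w_back, 0.5)
  expect_false(ws$out_of_base)
  # vertical trunk directly over the back ankle
  over_back <- make_test_frame(overrides = list(
    left_shoulder = c(40, 50), right_shoulder = c(40, 50),
    left_hip = c(40, 110), right_hip = c(40, 110), nose = c(50, 28),
    left_ankle = c(160, 210), right_ankle = c(40, 210)))
  expect_equal(weight_shift_back(over_back)$w_back, 1)
  # trunk tilted backward: independent analytic line-intersection oracle
  tilt <- 10 * pi / 180
  sx <- 100 - 60 * sin(tilt)   # shoulder moved back, trunk length kept
  fr <- make_test_frame(overrides = list(
    left_shoulder = c(sx, 110 - 60 * cos(tilt)),
    right_shoulder = c(sx, 110 - 60 * cos(tilt)),
    nose = c(115, 28),
    left_ankle = c(160, 210), right_ankle = c(40, 210)))
  ms <- c(sx, 110 - 60 * cos(tilt)); mh <- c(100, 110)
  slope <- (mh[1] - ms[1]) / (mh[2] - ms[2])
  x_int <- ms[1] + slope * (210 - ms[2])
  expect_equal(weight_shift_back(fr)$w_back, (x_int - 160) / (40 - 160),
               tolerance = 1e-12)
  expect_error(weight_shift_back(make_test_frame()), "degenerate|undetermined")
})

test_that("invisible-toe check matches boundary, clear cases, and an oracle", {
  # knee vertically above toe, eye vertically above knee: boundary -> hidden
  fr <- make_test_frame(overrides = list(
    left_eye = c(150, 24), left_knee = c(150, 160),
    left_foot_index = c(150, 214),
    left_ankle = c(140, 210), right_ankle = c(60, 210), nose = c(112, 28)))
  expect_true(toe_visibility(fr, front = "left", facing = 1))
  # knee well behind the toe: ray falls short -> visible
  fr2 <- make_test_frame(overrides = list(
    left_eye = c(110, 24), left_knee = c(112, 160),
    left_foot_index = c(180, 214),
    left_ankle = c(140, 210), right_ankle = c(60, 210)))
  expect_false(toe_visibility(fr2, front = "left", facing = 1))
  set.seed(33)
  for (i in 1:200) {
    eye <- c(runif(1, 80, 160), runif(1, 10, 40))
    knee <- c(runif(1, 80, 200), runif(1, 120, 180))
    toe <- c(runif(1, 80, 220), runif(1, 200, 230))
    fr3 <- make_test_frame(overrides = list(
      left_eye = eye, left_knee = knee, left_foot_index = toe))
    # oracle: parametric point on the eye->knee line at the toe's height
    lam <- (toe[2] - eye[2]) / (knee[2] - eye[2])
    x_at <- eye[1] + lam * (knee[1] - eye[1])
    expect_identical(toe_visibility(fr3, front = "left", facing = 1),
                     x_at >= toe[1])
  }
})

test_that("feature extraction is gated, complete, and mirror-symmetric", {
  dead <- make_test_frame(conf = 0)
  f <- extract_features(dead)
  expect_false(f$reliable)
  expect_true(is.na(f$F_left))
  sim <- simulate_stance(stance_preset("zenkutsu")$spec, n_frames = 1)
  fr <- sim$seq$frames[[1]]
  f1 <- extract_features(fr)
  expect_true(f1$reliable)
  expect_false(anyNA(unlist(f1[c("F_left", "F_right", "F_front", "F_back",
                                 "theta_body", "shin_left", "shin_right",
                                 "D_feet", "W_back")])))
  # mirror about a vertical axis: angles preserved, sides swapped
  pts <- unclass(fr)
  pts[, 1] <- 640 - pts[, 1]
  f2 <- extract_features(landmark_frame(pts, t_s = attr(fr, "t_s")))
  expect_equal(f2$facing, -f1$facing)
  expect_equal(f2$F_left, f1$F_left, tolerance = 1e-9)
  expect_equal(f2$theta_body, f1$theta_body, tolerance = 1e-9)
  expect_equal(f2$D_feet, f1$D_feet, tolerance = 1e-9)
  expect_equal(f2$front_leg, f1$front_leg)  # left stays front after mirroring
  expect_equal(f2$W_back, f1$W_back, tolerance = 1e-9)
})

test_that("angles and normalised distances are translation/scale invariant", {
  set.seed(34)
  sim <- simulate_stance(stance_preset("kokutsu")$spec, n_frames = 1)
  fr <- sim$seq$frames[[1]]
  f0 <- extract_features(fr)
  for (i in 1:10) {
    s <- runif(1, 0.3, 3); dx <- runif(2, -200, 200)
    pts <- unclass(fr)
    pts[, 1] <- pts[, 1] * s + dx[1]
    pts[, 2] <- pts[, 2] * s + dx[2]
    f <- extract_features(landmark_frame(pts, t_s = 0))
    for (field in c("F_left", "F_right", "theta_body", "shin_left",
                    "shin_right", "D_feet", "W_back"))
      expect_equal(f[[field]], f0[[field]], tolerance = 1e-9)
  }
})

test_that("jittered upright trunk stays within the 2-degree noise bound", {
  # Monte-Carlo: sigma = 1 px on a 200 px trunk
  set.seed(35)
  base <- make_test_frame(overrides = list(
    left_shoulder = c(100, 10), right_shoulder = c(100, 10),
    left_hip = c(100, 210), right_hip = c(100, 210)))
  devs <- replicate(200, {
    pts <- unclass(base)
    pts[, 1:2] <- pts[, 1:2] + rnorm(66, 0, 1)
    trunk_inclination(landmark_frame(pts))
  })
  expect_lt(mean(devs), 2)
})
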