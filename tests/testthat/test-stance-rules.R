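test_that("threshold constructor validates its domain", {
  expect_s3_class(stance_thresholds(), "stance_thresholds")
  expect_error(stance_thresholds(W_min = 0), "W_min")
  expect_error(stance_thresholds(W_min = 1.1), "W_min")
  expect_error(stance_thresholds(F_range_deg = c(90, 30)), "lo < hi")
  expect_error(stance_thresholds(T_upright_deg = -5))
})

test_that("hand-built feature vectors hit each rule and each near-miss", {
  thr <- stance_thresholds()
  # canonical zenkutsu: front 60, back 10, upright, wide base
  expect_equal(classify_stance(feat(F_left = 60, F_right = 10,
                                    D_feet = 1.4), thr)$label, "zenkutsu")
  # kokutsu: rear knee deep, weight back
  expect_equal(classify_stance(feat(F_left = 10, F_right = 60,
                                    front_leg = "left", D_feet = 1.2,
                                    W_back = 0.75), thr)$label, "kokutsu")
  # kiba: symmetric flexion over a wide base
  expect_equal(classify_stance(feat(F_left = 60, F_right = 60,
                                    D_feet = 1.8), thr)$label, "kiba")
  # near-misses: one predicate violated at a time
  expect_equal(classify_stance(feat(F_left = 60, F_right = 10,
                                    D_feet = 1.4, theta_body = 16),
                               thr)$label, "none")       # trunk tilt
  expect_equal(classify_stance(feat(F_left = 60, F_right = 10,
                                    D_feet = 0.89), thr)$label, "none")
  expect_equal(classify_stance(feat(F_left = 10, F_right = 60,
                                    front_leg = "left", W_back = 0.59),
                               thr)$label, "none")       # weight not back
  expect_equal(classify_stance(feat(F_left = 60, F_right = 60,
                                    D_feet = 1.29), thr)$label, "none")
  expect_equal(classify_stance(feat(F_left = 95, F_right = 95,
                                    D_feet = 1.8), thr)$label, "none")
})

test_that("boundary semantics: inclusive thresholds, strict flexion margin", {
  thr <- stance_thresholds()
  # flexion comparison is strict beyond eps: a gap of exactly eps is symmetric
  expect_equal(classify_stance(feat(F_left = 60, F_right = 55,
                                    D_feet = 1.4), thr)$label, "kiba")
  # just over eps -> asymmetric branch
  d <- classify_stance(feat(F_left = 60.01, F_right = 55, D_feet = 1.4), thr)
  expect_equal(d$label, "zenkutsu")
  # D and W comparisons are inclusive at the threshold
  expect_equal(classify_stance(feat(F_left = 60, F_right = 10,
                                    D_feet = 0.9), thr)$label, "zenkutsu")
  expect_equal(classify_stance(feat(F_left = 10, F_right = 60,
                                    front_leg = "left", W_back = 0.6),
                               thr)$label, "kokutsu")
  expect_equal(classify_stance(feat(F_left = 30, F_right = 30,
                                    D_feet = 1.3), thr)$label, "kiba")
  # trunk tolerance inclusive
  expect_equal(classify_stance(feat(F_left = 60, F_right = 10, D_feet = 1.4,
                                    theta_body = 15), thr)$label, "zenkutsu")
})

test_that("labels are mutually exclusive by construction (random property)", {
  thr <- stance_thresholds()
  set.seed(51)
  for (i in 1:500) {
    f <- feat(F_left = runif(1, 0, 120), F_right = runif(1, 0, 120),
              theta_body = runif(1, 0, 40), D_feet = runif(1, 0, 2.5),
              W_back = runif(1),
              front_leg = sample(c("left", "right"), 1))
    d <- classify_stance(f, thr)
    expect_true(d$label %in% c("zenkutsu", "kokutsu", "kiba", "none"))
    tr <- d$predicate_trace
    # symmetric and asymmetric predicates are never both evaluated
    if (isTRUE(tr["symmetric"])) {
      expect_true(all(is.na(tr[c("zd_flexion", "kd_flexion")])))
    } else {
      expect_true(all(is.na(tr[c("kiba_F_left", "kiba_D_feet")])))
      # ZD and KD flexion conditions are logically exclusive
      expect_false(isTRUE(tr["zd_flexion"]) && isTRUE(tr["kd_flexion"]))
    }
  }
})

test_that("unreliable frames classify as none without error", {
  d <- classify_stance(feat(reliable = FALSE))
  expect_equal(d$label, "none")
  expect_false(d$frame_reliable)
  d2 <- classify_stance(feat(F_left = NA_real_))
  expect_equal(d2$label, "none")
})

test_that("predicate trace explains a near-miss decision", {
  d <- classify_stance(feat(F_left = 60, F_right = 10, D_feet = 0.5))
  expect_equal(d$label, "none")
  expect_true(isTRUE(d$predicate_trace["zd_flexion"]))
  expect_false(isTRUE(d$predicate_trace["zd_D_feet"]))
  expect_output(print(d), "zd_D_feet=fail")
})

test_that("sequence classification is stable on noiseless generator scenes", {
  for (st in c("zenkutsu", "kokutsu", "kiba")) {
    sim <- simulate_stance(stance_preset(st)$spec, n_frames = 12)
    cl <- classify_sequence(sim$seq)
    expect_equal(cl$summary, st)
    expect_equal(unique(cl$per_frame$label), st)
    expect_equal(cl$n_reliable, 12L)
  }
  expect_error(classify_sequence(landmark_sequence(list())), "empty")
})

test_that("k_stable suppresses a majority that never persists", {
  # interleave single zenkutsu frames with kiba frames: zenkutsu is the
  # strict majority (8 vs 7) but never runs 3 in a row
  z <- simulate_stance(stance_preset("zenkutsu")$spec, n_frames = 8)$seq$frames
  k <- simulate_stance(stance_preset("kiba")$spec, n_frames = 7)$seq$frames
  mixed <- list()
  for (i in 1:7) {
    mixed[[2 * i - 1]] <- z[[i]]
    mixed[[2 * i]] <- k[[i]]
  }
  mixed[[15]] <- z[[8]]
  mixed <- lapply(seq_along(mixed), function(i) {
    landmark_frame(unclass(mixed[[i]]), t_s = (i - 1) / 30)
  })
  seqm <- landmark_sequence(mixed)
  expect_equal(classify_sequence(seqm, k_stable = 3L)$summary, "none")
  expect_equal(classify_sequence(seqm, k_stable = 1L)$summary, "zenkutsu")
})

test_that("vectorised rule evaluation matches the scalar classifier", {
  set.seed(52)
  thr <- stance_thresholds()
  rows <- lapply(1:200, function(i)
    feat(F_left = runif(1, 0, 120), F_right = runif(1, 0, 120),
         theta_body = runif(1, 0, 40), D_feet = runif(1, 0, 2.5),
         W_back = runif(1), front_leg = sample(c("left", "right"), 1)))
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  vec <- stancekit:::classify_feature_rows(df, thr)
  scal <- vapply(rows, function(r) classify_stance(r, thr)$label, character(1))
  expect_identical(vec, scal)
})

test_that("calibration recovers working thresholds from labelled features", {
  set.seed(53)
  frames <- list(); labels <- character(0)
  for (st in c("zenkutsu", "kokutsu", "kiba")) {
    sim <- simulate_stance(stance_preset(st)$spec, n_frames = 15,
                           noise = noise_model(jitter_sd_px = 1.5, seed = 53))
    frames <- c(frames, sim$seq$frames)
    labels <- c(labels, rep(st, 15))
  }
  ft <- do.call(rbind, lapply(frames, function(fr)
    as.data.frame(unclass(extract_features(fr)), stringsAsFactors = FALSE)))
  cal <- calibrate_thresholds(ft, labels)
  expect_s3_class(cal, "stance_calibration")
  expect_gte(cal$agreement, 0.9)
  expect_s3_class(cal$thresholds, "stance_thresholds")
  # the returned thresholds reproduce the reported training agreement
  expect_equal(mean(stancekit:::classify_feature_rows(ft, cal$thresholds) ==
                      labels), cal$agreement)
})

test_that("calibration errors are precise about coverage and emptiness", {
  ft <- as.data.frame(feat(F_left = 60, F_right = 10, D_feet = 1.4),
                      stringsAsFactors = FALSE)
  expect_error(calibrate_thresholds(ft, "zenkutsu"),
               "calibration-coverage error.*kokutsu")
  expect_error(calibrate_thresholds(ft[0, ], character(0)),
               "no training examples")
  expect_error(calibrate_thresholds(ft, c("zenkutsu", "kiba")), "lengths")
})

test_that("calibration tie-break is deterministic (first lattice maximum)", {
  set.seed(54)
  frames <- list(); labels <- character(0)
  for (st in c("zenkutsu", "kokutsu", "kiba")) {
    sim <- simulate_stance(stance_preset(st)$spec, n_frames = 4)
    frames <- c(frames, sim$seq$frames)
    labels <- c(labels, rep(st, 4))
  }
  ft <- do.call(rbind, lapply(frames, function(fr)
    as.data.frame(unclass(extract_features(fr)), stringsAsFactors = FALSE)))
  c1 <- calibrate_thresholds(ft, labels)
  c2 <- calibrate_thresholds(ft, labels)
  expect_identical(c1$lattice_index, c2$lattice_index)
  expect_identical(unclass(c1$thresholds), unclass(c2$thresholds))
})
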