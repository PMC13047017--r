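#' @title Rule-based stance classification
#' @description The three fundamental Shotokan stances are classified by
#'   conjunctions of threshold predicates over per-frame kinematic features.
#'   Zenkutsu Dachi (forward stance): front knee more flexed than the rear,
#'   upright trunk, minimum foot separation. Kokutsu Dachi (back stance):
#'   rear knee more flexed, upright trunk, posterior weight shift. Kiba
#'   Dachi (horse stance): both knees flexed within a target range over a
#'   wide base. A symmetric-versus-asymmetric branch on the left/right
#'   flexion difference makes the labels mutually exclusive by construction.
#' @name stance-rules
NULL

#' Stance decision thresholds
#'
#' Default values are calibrated on the package's synthetic generator, not
#' taken from any external study, and are exposed as configuration.
#'
#' @param T_upright_deg Allowed trunk-tilt half-width (deg); default 15.
#' @param D_min Minimum foot separation for Zenkutsu (trunk lengths);
#'   default 0.9.
#' @param W_min Minimum posterior weight shift for Kokutsu (proportion in
#'   (0, 1\]); default 0.6.
#' @param F_range_deg Target knee-flexion window for Kiba, `c(lo, hi)` in
#'   degrees; default c(30, 90).
#' @param D_kiba_min Minimum lateral separation for Kiba (trunk lengths);
#'   default 1.3.
#' @param eps_flex_deg Asymmetry margin on the front/back flexion
#'   comparison (deg); default 5.
#' @return A `stance_thresholds` list.
#' @export
stance_thresholds <- function(T_upright_deg = 15, D_min = 0.9, W_min = 0.6,
                              F_range_deg = c(30, 90), D_kiba_min = 1.3,
                              eps_flex_deg = 5) {
  stopifnot(T_upright_deg > 0, D_min > 0, D_kiba_min > 0, eps_flex_deg > 0)
  if (length(F_range_deg) != 2L || F_range_deg[1] >= F_range_deg[2])
    stop("F_range_deg must be c(lo, hi) with lo < hi", call. = FALSE)
  if (W_min <= 0 || W_min > 1)
    stop("W_min must lie in (0, 1]", call. = FALSE)
  structure(list(T_upright_deg = T_upright_deg, D_min = D_min, W_min = W_min,
                 F_range_deg = as.numeric(F_range_deg),
                 D_kiba_min = D_kiba_min, eps_flex_deg = eps_flex_deg),
            class = "stance_thresholds")
}

#' Classify one frame's features into a stance label
#'
#' Evaluation order: if `|F_left - F_right| <= eps_flex` the symmetric
#' branch tests the Kiba rule; otherwise the asymmetric branch tests
#' Zenkutsu (`F_front > F_back + eps`, trunk within tolerance, separation
#' at least `D_min`) and Kokutsu (`F_back > F_front + eps`, trunk within
#' tolerance, `W_back >= W_min`). `none` when no rule fires. The full
#' predicate trace is retained for interpretability.
#'
#' @param f A `kinematic_features` object (or compatible list).
#' @param thr A [stance_thresholds()] object.
#' @return A `stance_decision`: list with `label` (one of `"zenkutsu"`,
#'   `"kokutsu"`, `"kiba"`, `"none"`), `predicate_trace` (named logical),
#'   and `frame_reliable`.
#' @export
classify_stance <- function(f, thr = stance_thresholds()) {
  trace <- c(symmetric = NA, kiba_F_left = NA, kiba_F_right = NA,
             kiba_D_feet = NA, zd_flexion = NA, zd_trunk = NA, zd_D_feet = NA,
             kd_flexion = NA, kd_trunk = NA, kd_W_back = NA)
  mk <- function(label, reliable = TRUE)
    structure(list(label = label, predicate_trace = trace,
                   frame_reliable = reliable), class = "stance_decision")
  if (!isTRUE(f$reliable)) return(mk("none", reliable = FALSE))
  if (is.na(f$F_left) || is.na(f$F_right)) return(mk("none", reliable = FALSE))
  sym <- abs(f$F_left - f$F_right) <= thr$eps_flex_deg
  trace["symmetric"] <- sym
  label <- "none"
  if (sym) {
    trace["kiba_F_left"] <- f$F_left >= thr$F_range_deg[1] &&
      f$F_left <= thr$F_range_deg[2]
    trace["kiba_F_right"] <- f$F_right >= thr$F_range_deg[1] &&
      f$F_right <= thr$F_range_deg[2]
    trace["kiba_D_feet"] <- !is.na(f$D_feet) && f$D_feet >= thr$D_kiba_min
    if (isTRUE(trace["kiba_F_left"]) && isTRUE(trace["kiba_F_right"]) &&
        isTRUE(trace["kiba_D_feet"]))
      label <- "kiba"
  } else {
    if (f$front_leg == "undetermined" || is.na(f$F_front))
      return(mk("none"))
    trace["zd_flexion"] <- f$F_front > f$F_back + thr$eps_flex_deg
    trace["zd_trunk"] <- !is.na(f$theta_body) &&
      f$theta_body <= thr$T_upright_deg
    trace["zd_D_feet"] <- !is.na(f$D_feet) && f$D_feet >= thr$D_min
    trace["kd_flexion"] <- f$F_back > f$F_front + thr$eps_flex_deg
    trace["kd_trunk"] <- trace["zd_trunk"]
    trace["kd_W_back"] <- !is.na(f$W_back) && f$W_back >= thr$W_min
    if (isTRUE(trace["zd_flexion"]) && isTRUE(trace["zd_trunk"]) &&
        isTRUE(trace["zd_D_feet"])) {
      label <- "zenkutsu"
    } else if (isTRUE(trace["kd_flexion"]) && isTRUE(trace["kd_trunk"]) &&
               isTRUE(trace["kd_W_back"])) {
      label <- "kokutsu"
    }
  }
  structure(list(label = label, predicate_trace = trace,
                 frame_reliable = TRUE), class = "stance_decision")
}

#' @export
print.stance_decision <- function(x, ...) {
  cat(sprintf("<stance_decision> %s (frame %s)\n", x$label,
              if (x$frame_reliable) "reliable" else "unreliable"))
  tr <- x$predicate_trace[!is.na(x$predicate_trace)]
  if (length(tr))
    cat("  ", paste(names(tr), ifelse(tr, "pass", "fail"), sep = "=",
                    collapse = " "), "\n")
  invisible(x)
}

# vectorised rule evaluation over a feature table (used by calibration)
classify_feature_rows <- function(df, thr) {
  n <- nrow(df)
  lab <- rep("none", n)
  rel <- df$reliable & !is.na(df$F_left) & !is.na(df$F_right)
  sym <- rel & abs(df$F_left - df$F_right) <= thr$eps_flex_deg
  kiba <- sym &
    df$F_left >= thr$F_range_deg[1] & df$F_left <= thr$F_range_deg[2] &
    df$F_right >= thr$F_range_deg[1] & df$F_right <= thr$F_range_deg[2] &
    !is.na(df$D_feet) & df$D_feet >= thr$D_kiba_min
  asym <- rel & !sym & df$front_leg != "undetermined" & !is.na(df$F_front)
  trunk_ok <- !is.na(df$theta_body) & df$theta_body <= thr$T_upright_deg
  zd <- asym & df$F_front > df$F_back + thr$eps_flex_deg & trunk_ok &
    !is.na(df$D_feet) & df$D_feet >= thr$D_min
  kd <- asym & df$F_back > df$F_front + thr$eps_flex_deg & trunk_ok &
    !is.na(df$W_back) & df$W_back >= thr$W_min
  lab[which(kiba)] <- "kiba"
  lab[which(zd)] <- "zenkutsu"
  lab[which(kd)] <- "kokutsu"
  lab
}

#' Classify a whole landmark sequence
#'
#' Smooths (optionally), extracts features per frame, classifies each frame,
#' and reports a summary label: the majority label over reliable frames,
#' reported only when that label persists for at least `k_stable`
#' consecutive reliable frames; otherwise `"none"`.
#'
#' @param seq A `landmark_sequence`.
#' @param thr A [stance_thresholds()].
#' @param filter_cfg Optional [filter_config()] applied before extraction.
#' @param min_conf Confidence gate.
#' @param k_stable Stability window in frames; default 5.
#' @return A `stance_classification`: list with `per_frame` (data.frame of
#'   t, label, reliable), `summary` label, and `n_reliable`.
#' @export
classify_sequence <- function(seq, thr = stance_thresholds(),
                              filter_cfg = NULL, min_conf = 0.5,
                              k_stable = 5L) {
  stopifnot(inherits(seq, "landmark_sequence"))
  if (length(seq$frames) == 0L)
    stop("empty sequence", call. = FALSE)
  if (!is.null(filter_cfg)) seq <- smooth_sequence(seq, filter_cfg)
  ft <- feature_table(seq, min_conf)
  labels <- vapply(seq_len(nrow(ft)), function(i) {
    classify_stance(as.list(ft[i, ]), thr)$label
  }, character(1))
  per_frame <- data.frame(t_s = ft$t_s, label = labels,
                          reliable = ft$reliable)
  rel_labels <- labels[ft$reliable]
  if (length(rel_labels) == 0L) {
    res <- list(per_frame = per_frame, summary = "none", n_reliable = 0L,
                diagnostic = "no reliable frames")
    class(res) <- "stance_classification"
    return(res)
  }
  tab <- sort(table(rel_labels), decreasing = TRUE)
  maj <- names(tab)[1]
  runs <- rle(rel_labels)
  stable <- any(runs$lengths[runs$values == maj] >= k_stable)
  res <- list(per_frame = per_frame,
              summary = if (stable) maj else "none",
              n_reliable = length(rel_labels))
  class(res) <- "stance_classification"
  res
}

#' @export
print.stance_classification <- function(x, ...) {
  cat(sprintf("<stance_classification> summary: %s (%d/%d frames reliable)\n",
              x$summary, x$n_reliable, nrow(x$per_frame)))
  print(table(x$per_frame$label))
  invisible(x)
}

# documented calibration lattice, iterated in this order; first maximum wins
calibration_lattice <- function() {
  expand.grid(T_upright_deg = c(10, 15, 20),
              D_min = c(0.6, 0.8, 1.0, 1.2),
              W_min = c(0.4, 0.5, 0.6, 0.7),
              F_lo = c(20, 30, 40),
              F_hi = c(80, 90, 100),
              D_kiba_min = c(1.0, 1.2, 1.4),
              eps_flex_deg = 5,
              KEEP.OUT.ATTRS = FALSE)
}

#' Data-driven threshold calibration
#'
#' Exhaustive grid search over a documented parameter lattice, maximising
#' stance-label agreement with the supplied reference labels. Ties are
#' broken deterministically by the first lattice point in iteration order.
#'
#' @param features A feature data.frame (as from [feature_table()]).
#' @param labels Character vector of reference labels (`"zenkutsu"`,
#'   `"kokutsu"`, `"kiba"`), one per row of `features`. All three classes
#'   must be represented.
#' @return A `stance_calibration` object: `thresholds`
#'   ([stance_thresholds()]), `agreement` (training proportion), `n`, and
#'   the index of the winning lattice point.
#' @export
calibrate_thresholds <- function(features, labels) {
  if (is.null(features) || nrow(features) == 0L)
    stop("calibration error: no training examples", call. = FALSE)
  if (nrow(features) != length(labels))
    stop("features and labels lengths differ", call. = FALSE)
  classes <- c("zenkutsu", "kokutsu", "kiba")
  missing <- setdiff(classes, unique(labels))
  if (length(missing))
    stop("calibration-coverage error: no examples for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lat <- calibration_lattice()
  best_i <- NA_integer_; best_agree <- -1
  for (i in seq_len(nrow(lat))) {
    p <- lat[i, ]
    if (p$F_lo >= p$F_hi) next
    thr <- stance_thresholds(T_upright_deg = p$T_upright_deg,
                             D_min = p$D_min, W_min = p$W_min,
                             F_range_deg = c(p$F_lo, p$F_hi),
                             D_kiba_min = p$D_kiba_min,
                             eps_flex_deg = p$eps_flex_deg)
    agree <- mean(classify_feature_rows(features, thr) == labels)
    if (agree > best_agree) {
      best_agree <- agree; best_i <- i
    }
  }
  p <- lat[best_i, ]
  out <- list(thresholds = stance_thresholds(
                T_upright_deg = p$T_upright_deg, D_min = p$D_min,
                W_min = p$W_min, F_range_deg = c(p$F_lo, p$F_hi),
                D_kiba_min = p$D_kiba_min, eps_flex_deg = p$eps_flex_deg),
              agreement = best_agree, n = nrow(features),
              lattice_index = best_i)
  class(out) <- "stance_calibration"
  out
}

#' @export
print.stance_calibration <- function(x, ...) {
  cat(sprintf("<stance_calibration> training agreement %.1f%% on %d examples\n",
              100 * x$agreement, x$n))
  thr <- x$thresholds
  cat(sprintf("  T_upright=%g deg, D_min=%g, W_min=%g, F_range=[%g, %g] deg, D_kiba_min=%g\n",
              thr$T_upright_deg, thr$D_min, thr$W_min, thr$F_range_deg[1],
              thr$F_range_deg[2], thr$D_kiba_min))
  invisible(x)
}
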