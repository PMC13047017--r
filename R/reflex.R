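#' @title Reaction-time measurement for the punch task
#' @description In the reflex task the subject punches when a target
#'   appears. Punch detection tracks forward hand movement relative to the
#'   torso: the wrist's displacement along the facing direction, measured
#'   from the mid-shoulder and normalised by trunk length. Reaction time is
#'   the interval from the stimulus to the first sustained
#'   threshold-crossing frame; its resolution is inherently quantised by
#'   the camera frame rate.
#' @name reflex
NULL

#' Reflex-task configuration
#'
#' @param delta_disp Displacement threshold in trunk lengths (> 0);
#'   default 0.5.
#' @param sustain_frames Consecutive frames the displacement must stay
#'   above threshold (>= 1); default 2.
#' @param baseline_window_s Pre-stimulus averaging window in seconds;
#'   default 0.5.
#' @param timeout_s Maximum wait after the stimulus (seconds); default 2.
#' @param hand `"left"`, `"right"`, or `"either"` (the maximum of the two
#'   displacements); default `"either"`.
#' @return A `reflex_config` list.
#' @export
reflex_config <- function(delta_disp = 0.5, sustain_frames = 2L,
                          baseline_window_s = 0.5, timeout_s = 2,
                          hand = c("either", "left", "right")) {
  hand <- match.arg(hand)
  if (delta_disp <= 0 || sustain_frames < 1L || timeout_s <= 0 ||
      baseline_window_s <= 0)
    stop("config error: delta_disp > 0, sustain_frames >= 1, windows > 0",
         call. = FALSE)
  structure(list(delta_disp = delta_disp,
                 sustain_frames = as.integer(sustain_frames),
                 baseline_window_s = baseline_window_s,
                 timeout_s = timeout_s, hand = hand),
            class = "reflex_config")
}

# forward wrist displacement (px) per frame, for one hand
wrist_forward_disp <- function(frame, hand, facing) {
  (frame[paste0(hand, "_wrist"), "x"] - mid_shoulder(frame)[1]) * facing
}

#' Reaction time from stimulus to punch detection
#'
#' The pre-stimulus displacement baseline is subtracted so that forward
#' guard positions or drift before the stimulus cannot trigger detection.
#' Detection fires at the first frame after the stimulus whose
#' baseline-corrected forward displacement reaches `delta_disp` trunk
#' lengths and stays there for `sustain_frames` consecutive frames.
#'
#' @param seq A `landmark_sequence`.
#' @param stimulus_t Stimulus time in seconds (within the sequence span).
#' @param cfg A [reflex_config()].
#' @return A `reaction_result`: `detected` flag, `rt_s` (seconds, `NA` on
#'   timeout), `t_detect`, and the `stimulus_t`.
#' @export
reaction_time <- function(seq, stimulus_t, cfg = reflex_config()) {
  stopifnot(inherits(seq, "landmark_sequence"), inherits(cfg, "reflex_config"))
  t <- sequence_times(seq)
  if (length(t) == 0L || stimulus_t < min(t) || stimulus_t > max(t))
    stop("stimulus_t outside the sequence span", call. = FALSE)
  hands <- if (cfg$hand == "either") c("left", "right") else cfg$hand
  facing <- facing_direction(seq$frames[[1L]])
  tl <- trunk_length_px(seq$frames[[1L]])
  disp <- vapply(seq$frames, function(fr) {
    max(vapply(hands, function(h) wrist_forward_disp(fr, h, facing),
               numeric(1)))
  }, numeric(1)) / tl
  pre <- which(t >= stimulus_t - cfg$baseline_window_s & t < stimulus_t)
  if (length(pre) == 0L)
    stop("baseline error: no frames in the pre-stimulus window",
         call. = FALSE)
  baseline <- mean(disp[pre])
  post <- which(t > stimulus_t & t <= stimulus_t + cfg$timeout_s)
  above <- (disp[post] - baseline) >= cfg$delta_disp
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= cfg$sustain_frames)
  res <- list(detected = FALSE, rt_s = NA_real_, t_detect = NA_real_,
              stimulus_t = stimulus_t)
  if (length(hit)) {
    i0 <- post[starts[hit[1L]]]
    res$detected <- TRUE
    res$t_detect <- t[i0]
    res$rt_s <- t[i0] - stimulus_t
  }
  class(res) <- "reaction_result"
  res
}

#' @export
print.reaction_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<reaction_result> RT = %.3f s (stimulus at %.3f s)\n",
                x$rt_s, x$stimulus_t))
  else
    cat(sprintf("<reaction_result> timeout (stimulus at %.3f s)\n",
                x$stimulus_t))
  invisible(x)
}
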