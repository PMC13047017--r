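#' @title Temporal smoothing of landmark trajectories
#' @description Smoothing is applied per landmark, per coordinate (x and y
#'   only); z and confidence pass through untouched. Window filters (moving
#'   average, median) use symmetric windows truncated at the sequence edges.
#'   The one-euro filter is causal, matching its real-time origin: an
#'   adaptive exponential low-pass whose cutoff rises with signal speed, the
#'   standard choice for pose-landmark jitter.
#' @name filtering
NULL

#' Smoothing configuration
#'
#' @param kind One of `"none"`, `"moving_average"`, `"median"`, `"one_euro"`.
#' @param window Odd window length in frames (window filters); default 5.
#' @param min_cutoff Minimum cutoff frequency in Hz (one-euro); default 1.0.
#' @param beta Speed coefficient (one-euro, unitless); default 0.007.
#' @param d_cutoff Derivative cutoff in Hz (one-euro); default 1.0.
#' @return A `filter_config` list.
#' @export
filter_config <- function(kind = c("none", "moving_average", "median",
                                   "one_euro"),
                          window = 5L, min_cutoff = 1.0, beta = 0.007,
                          d_cutoff = 1.0) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (kind %in% c("moving_average", "median")) {
    if (is.na(window) || window < 1L || window %% 2L == 0L)
      stop("config error: window must be odd and >= 1", call. = FALSE)
  }
  if (min_cutoff <= 0 || d_cutoff <= 0)
    stop("config error: cutoffs must be > 0", call. = FALSE)
  structure(list(kind = kind, window = window, min_cutoff = min_cutoff,
                 beta = beta, d_cutoff = d_cutoff),
            class = "filter_config")
}

# symmetric window filter with edge truncation
window_filter <- function(x, window, fun) {
  n <- length(x)
  if (n == 0L || window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    fun(x[lo:hi])
  }, numeric(1))
}

one_euro_alpha <- function(cutoff, dt) {
  tau <- 1 / (2 * pi * cutoff)
  1 / (1 + tau / dt)
}

# causal one-euro filter over an irregularly sampled trajectory
one_euro_filter <- function(x, t, min_cutoff, beta, d_cutoff) {
  n <- length(x)
  if (n == 0L) return(x)
  out <- numeric(n)
  out[1] <- x[1]
  dx_hat <- 0
  for (i in seq_len(n)[-1]) {
    dt <- t[i] - t[i - 1]
    if (dt <= 0) dt <- .Machine$double.eps
    dx <- (x[i] - out[i - 1]) / dt
    a_d <- one_euro_alpha(d_cutoff, dt)
    dx_hat <- a_d * dx + (1 - a_d) * dx_hat
    cutoff <- min_cutoff + beta * abs(dx_hat)
    a <- one_euro_alpha(cutoff, dt)
    out[i] <- a * x[i] + (1 - a) * out[i - 1]
  }
  out
}

#' Smooth the landmark trajectories of a sequence
#'
#' @param seq A `landmark_sequence`.
#' @param cfg A [filter_config()].
#' @return A `landmark_sequence` of the same length and timestamps with
#'   smoothed x/y coordinates; z and confidence are unchanged.
#' @export
smooth_sequence <- function(seq, cfg = filter_config()) {
  stopifnot(inherits(seq, "landmark_sequence"), inherits(cfg, "filter_config"))
  n <- length(seq$frames)
  if (cfg$kind == "none" || n == 0L) return(seq)
  t <- sequence_times(seq)
  frames <- seq$frames
  for (j in seq_len(N_LANDMARKS)) {
    for (coord in c("x", "y")) {
      x <- vapply(frames, function(fr) fr[j, coord], numeric(1))
      xs <- switch(cfg$kind,
        moving_average = window_filter(x, cfg$window, mean),
        median = window_filter(x, cfg$window, stats::median),
        one_euro = one_euro_filter(x, t, cfg$min_cutoff, cfg$beta,
                                   cfg$d_cutoff))
      for (i in seq_len(n)) frames[[i]][j, coord] <- xs[i]
    }
  }
  landmark_sequence(frames, fps_nominal = seq$fps_nominal)
}

#' Effect of smoothing on angular features
#'
#' Runs feature extraction before and after smoothing and summarises the
#' per-frame differences of the main angular features, supporting
#' pre-versus-post smoothing ablation comparisons.
#'
#' @param seq A `landmark_sequence`.
#' @param cfg A [filter_config()].
#' @param min_conf Confidence gate.
#' @return A data.frame with one row per feature: mean and max absolute
#'   change in degrees over frames reliable in both passes.
#' @export
smoothing_ablation <- function(seq, cfg, min_conf = 0.5) {
  pre <- feature_table(seq, min_conf)
  post <- feature_table(smooth_sequence(seq, cfg), min_conf)
  feats <- c("F_left", "F_right", "theta_body", "shin_left", "shin_right")
  ok <- pre$reliable & post$reliable
  rows <- lapply(feats, function(f) {
    d <- abs(post[[f]][ok] - pre[[f]][ok])
    data.frame(feature = f,
               mean_abs_change_deg = if (any(ok)) mean(d, na.rm = TRUE) else NA_real_,
               max_abs_change_deg = if (any(ok)) max(d, na.rm = TRUE) else NA_real_,
               n_frames = sum(ok))
  })
  do.call(rbind, rows)
}
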