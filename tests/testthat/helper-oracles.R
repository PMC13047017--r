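# Independent oracles used across the suite. These deliberately use
# different formulations from the package internals they check.

# law-of-cosines angle at vertex b, degrees
loc_angle <- function(a, b, c) {
  ab <- sqrt(sum((a - b)^2))
  cb <- sqrt(sum((c - b)^2))
  ac <- sqrt(sum((a - c)^2))
  acos(min(1, max(-1, (ab^2 + cb^2 - ac^2) / (2 * ab * cb)))) * 180 / pi
}

# reference one-euro filter, written from the published recursion with the
# r/(r+1) smoothing-factor form
ref_one_euro <- function(x, t, min_cutoff = 1, beta = 0.007, d_cutoff = 1) {
  n <- length(x)
  if (n == 0L) return(x)
  y <- numeric(n)
  y[1] <- x[1]
  dprev <- 0
  for (i in seq_len(n)[-1]) {
    dt <- max(t[i] - t[i - 1], .Machine$double.eps)
    r_d <- 2 * pi * d_cutoff * dt
    a_d <- r_d / (r_d + 1)
    d <- (x[i] - y[i - 1]) / dt
    dhat <- a_d * d + (1 - a_d) * dprev
    dprev <- dhat
    fc <- min_cutoff + beta * abs(dhat)
    r <- 2 * pi * fc * dt
    a <- r / (r + 1)
    y[i] <- a * x[i] + (1 - a) * y[i - 1]
  }
  y
}

# repetition count as the number of bottom-state runs bracketed by
# top-state runs, via run-length encoding of the three-level state signal
# (valid against the state machine at dwell 1, zero refractory)
oracle_count_reps <- function(angles, top, bottom) {
  if (!length(angles)) return(0L)
  s <- ifelse(angles >= top, "T", ifelse(angles <= bottom, "B", "M"))
  r <- rle(s)$values
  r <- r[r != "M"]
  if (!length(r)) return(0L)
  r <- rle(r)$values
  n <- length(r)
  if (n < 3L) return(0L)
  sum(vapply(2:(n - 1), function(i)
    r[i] == "B" && r[i - 1] == "T" && r[i + 1] == "T", logical(1)))
}

# random piecewise-linear angle signal sampled at frame times
random_pl_signal <- function(n_knots = 8, n_frames = 120, lo = 40, hi = 180) {
  kt <- sort(c(0, stats::runif(n_knots - 2), 1))
  kv <- stats::runif(n_knots, lo, hi)
  tt <- seq(0, 1, length.out = n_frames)
  data.frame(t_s = tt * 4,
             angle_deg = stats::approx(kt, kv, xout = tt)$y,
             gate = TRUE)
}
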