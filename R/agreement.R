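#' @title Method-agreement statistics
#' @description Validation statistics for comparing app-derived joint angles
#'   and stance labels against expert reference annotations: mean absolute
#'   error, root-mean-square error, Bland-Altman bias and limits of
#'   agreement, Pearson correlation with a Fisher-z confidence interval,
#'   and the two-way random-effects absolute-agreement single-measure
#'   intraclass correlation ICC(2,1) with McGraw-Wong confidence limits.
#' @name agreement
NULL

check_pairs <- function(theta_app, theta_expert, min_n = 1L) {
  if (length(theta_app) != length(theta_expert))
    stop("paired angle vectors must have equal length", call. = FALSE)
  if (length(theta_app) < min_n)
    stop("need at least ", min_n, " angle pair(s)", call. = FALSE)
  invisible(NULL)
}

#' Mean absolute error of paired angles
#'
#' `MAE = sum(|theta_app - theta_expert|) / N`, with the sample standard
#' deviation (n - 1 denominator) of the absolute errors as spread. No
#' outlier exclusion is applied.
#'
#' @param theta_app,theta_expert Paired angle vectors (degrees).
#' @return List with `mae_deg` and `sd_abs_err_deg` (`NA` when n < 2).
#' @export
angle_mae <- function(theta_app, theta_expert) {
  check_pairs(theta_app, theta_expert, 1L)
  e <- abs(theta_app - theta_expert)
  list(mae_deg = mean(e),
       sd_abs_err_deg = if (length(e) >= 2L) stats::sd(e) else NA_real_)
}

#' Root-mean-square error of paired angles
#'
#' @inheritParams angle_mae
#' @return RMSE in degrees.
#' @export
angle_rmse <- function(theta_app, theta_expert) {
  check_pairs(theta_app, theta_expert, 1L)
  sqrt(mean((theta_app - theta_expert)^2))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences `d = theta_app - theta_expert`; bias is `mean(d)` and the
#' limits of agreement are `bias +/- 1.96 * sd(d)` (sample SD).
#'
#' @inheritParams angle_mae
#' @return List with `bias_deg`, `loa_low_deg`, `loa_high_deg`.
#' @export
bland_altman <- function(theta_app, theta_expert) {
  check_pairs(theta_app, theta_expert, 2L)
  d <- theta_app - theta_expert
  bias <- mean(d); s <- stats::sd(d)
  list(bias_deg = bias, loa_low_deg = bias - 1.96 * s,
       loa_high_deg = bias + 1.96 * s)
}

#' Pearson correlation with Fisher-z 95% confidence interval
#'
#' @inheritParams angle_mae
#' @param conf_level Confidence level; default 0.95.
#' @return List with `r`, `ci_low`, `ci_high`.
#' @export
pearson_ci <- function(theta_app, theta_expert, conf_level = 0.95) {
  check_pairs(theta_app, theta_expert, 3L)
  if (stats::sd(theta_app) == 0 || stats::sd(theta_expert) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- stats::cor(theta_app, theta_expert)
  n <- length(theta_app)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares (rows = subjects, columns
#' = raters): `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Confidence limits follow the McGraw-Wong F-based construction.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 2 of each).
#' @param conf_level Confidence level; default 0.95.
#' @return List with `icc`, `ci_low`, `ci_high`, and the mean squares. When
#'   between-subject variance is zero the ICC is flagged undefined
#'   (`icc = NA`, `degenerate = TRUE`).
#' @export
icc_absolute <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= .Machine$double.eps * abs(grand + 1) || denom == 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                msr = msr, msc = msc, mse = mse, degenerate = TRUE))
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  ci_low <- NA_real_; ci_high <- NA_real_
  if (mse > 0) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else if (icc == 1) {
    ci_low <- 1; ci_high <- 1
  }
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       msr = msr, msc = msc, mse = mse, degenerate = FALSE)
}

#' Full agreement report for paired angles
#'
#' @inheritParams angle_mae
#' @return An `agreement_report` list: MAE and SD of absolute errors, RMSE,
#'   Pearson r with CI, Bland-Altman bias and limits of agreement.
#' @export
agreement_report <- function(theta_app, theta_expert) {
  check_pairs(theta_app, theta_expert, 3L)
  m <- angle_mae(theta_app, theta_expert)
  ba <- bland_altman(theta_app, theta_expert)
  pc <- pearson_ci(theta_app, theta_expert)
  out <- list(n = length(theta_app),
              mae_deg = m$mae_deg, sd_abs_err_deg = m$sd_abs_err_deg,
              rmse_deg = angle_rmse(theta_app, theta_expert),
              pearson_r = pc$r, r_ci95 = c(pc$ci_low, pc$ci_high),
              ba_bias_deg = ba$bias_deg, ba_loa_low_deg = ba$loa_low_deg,
              ba_loa_high_deg = ba$loa_high_deg)
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d angle pairs\n", x$n))
  cat(sprintf("  MAE %.2f deg (SD of |err| %.2f), RMSE %.2f deg\n",
              x$mae_deg, x$sd_abs_err_deg, x$rmse_deg))
  cat(sprintf("  Pearson r %.3f [%.3f, %.3f]\n", x$pearson_r,
              x$r_ci95[1], x$r_ci95[2]))
  cat(sprintf("  Bland-Altman bias %.2f deg, LoA [%.2f, %.2f]\n",
              x$ba_bias_deg, x$ba_loa_low_deg, x$ba_loa_high_deg))
  invisible(x)
}

#' Load the bundled pilot stance-comparison table
#'
#' A nine-frame single-subject comparison of app-detected and
#' expert-annotated stance labels and knee/shin angles from lateral-view
#' stance holds. Two rows carry `parse_ambiguous = TRUE`: their transcribed
#' angle digit grouping is typographically ambiguous at the source, so
#' strict angle checks should exclude them; stance and side labels are
#' unambiguous on all nine rows.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return Data.frame with columns `side_detected`, `side_correct`,
#'   `stance_detected`, `stance_expert`, `knee_left_deg`, `shin_left_deg`,
#'   `knee_right_deg`, `shin_right_deg`, `parse_ambiguous`.
#' @export
load_stance_comparison <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pilot_stance_comparison.csv",
                        package = "stancekit", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("side_detected", "side_correct", "stance_detected",
              "stance_expert", "knee_left_deg", "shin_left_deg",
              "knee_right_deg", "shin_right_deg", "parse_ambiguous")
  if (!all(needed %in% names(df)))
    stop("stance comparison table is missing required columns", call. = FALSE)
  df
}

#' Stance and side agreement counts
#'
#' @param rows A stance-comparison data.frame (see
#'   [load_stance_comparison()]).
#' @return List with `n_label_match`, `n_side_correct`, `n_total`.
#' @export
stance_agreement <- function(rows) {
  list(n_label_match = sum(rows$stance_detected == rows$stance_expert),
       n_side_correct = sum(tolower(rows$side_correct) %in%
                              c("yes", "true", "1")),
       n_total = nrow(rows))
}
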