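#' Detrend an activity series by first differences
#'
#' Consecutive first differences remove slow trends and (approximately) the
#' diurnal level component, leaving a stationary series whose spread
#' reflects short-term variability of activity. Differences are never taken
#' across a gap larger than 1.5 times the nominal 10-minute cadence, and the
#' pre- and post-attachment segments are differenced separately (no
#' difference spans `t0`); each difference is timestamped at the later point
#' of its pair.
#'
#' @param series An [activity_series()] (already restricted to one segment).
#' @param segment Label recorded on the result: `"pre"`, `"post"`,
#'   `"cohort_average"` or `"all"`.
#' @param gap_factor Differences are suppressed across gaps wider than
#'   `gap_factor` times the nominal interval (default 1.5).
#' @return An object of class `detrended_series` with elements `cow_id`,
#'   `time`, `diffs` and `segment`.
#' @export
first_differences <- function(series, segment = "all", gap_factor = 1.5) {
  stopifnot(inherits(series, "activity_series"))
  n <- length(series$values)
  if (n < 2L)
    stopf("cow %s, segment '%s': need at least 2 points to difference (have %d)",
          series$cow_id, segment, n)
  dt <- diff(as.numeric(series$time))
  ok <- dt <= gap_factor * series$interval
  d <- diff(series$values)[ok]
  tm <- series$time[-1L][ok]
  if (!length(d))
    stopf("cow %s, segment '%s': no consecutive point pairs within gap tolerance",
          series$cow_id, segment)
  structure(list(cow_id = series$cow_id, time = tm, diffs = d,
                 segment = segment, interval = series$interval),
            class = "detrended_series")
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("<detrended_series> cow %s, segment '%s': %d first differences\n",
              x$cow_id, x$segment, length(x$diffs)))
  invisible(x)
}

# Dickey-Fuller tau_mu quantiles (regression with constant, no trend),
# indexed by series length; interpolated two ways as in standard practice.
.adf_table <- list(
  n = c(25, 50, 100, 250, 500, Inf),
  probs = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  q = rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37,  0.00,  0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23, 0.60))
)

#' Augmented Dickey--Fuller stationarity check
#'
#' Confirms that a detrended series is stationary before its variability is
#' tested. Fits the augmented Dickey--Fuller regression with a constant and
#' no trend, with lag order `floor((n - 1)^(1/3))`, and interpolates the
#' p-value from the standard Dickey--Fuller tau (constant case) quantile
#' table; p-values outside the tabulated range \[0.01, 0.99\] are clipped.
#' The pass decision compares the test statistic with the interpolated
#' critical value at `level`, so it remains exact at the table boundary.
#'
#' @param detrended A `detrended_series` (or numeric vector) of length >= 20.
#' @param level Significance level in (0, 1); default 0.01. The series
#'   counts as stationary when the unit-root null is rejected at `level`.
#' @return List of class `stationarity_result`: `statistic`, `p_value`,
#'   `lag_order`, `n_used`, `passed`.
#' @export
adf_stationarity_check <- function(detrended, level = 0.01) {
  if (!is_scalar_num(level) || level <= 0 || level >= 1)
    stopf("`level` must be a single number strictly between 0 and 1")
  x <- if (inherits(detrended, "detrended_series")) detrended$diffs else as.numeric(detrended)
  n <- length(x)
  if (n < 20L) stopf("need at least 20 observations for the ADF check (have %d)", n)
  if (stats::var(x) == 0)
    stopf("degenerate (constant) series: stationarity check undefined")
  k <- max(0L, floor((n - 1)^(1 / 3)))
  dx <- diff(x)
  m <- length(dx) - k
  y <- dx[(k + 1L):length(dx)]
  X <- cbind(1, x[(k + 1L):(n - 1L)])
  if (k > 0L)
    X <- cbind(X, vapply(seq_len(k), function(j) dx[(k + 1L - j):(length(dx) - j)],
                         numeric(m)))
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- m - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2L, 2L])
  stat <- fit$coefficients[2L] / se
  tab <- .adf_table
  qs <- vapply(seq_along(tab$probs),
               function(j) approx(tab$n, tab$q[, j], xout = n, rule = 2)$y,
               numeric(1))
  p <- approx(qs, tab$probs, xout = stat, rule = 2)$y
  crit <- approx(tab$probs, qs, xout = min(max(level, 0.01), 0.99), rule = 2)$y
  structure(list(statistic = unname(stat), p_value = unname(p),
                 lag_order = k, n_used = m, level = level,
                 passed = unname(stat < crit)),
            class = "stationarity_result")
}

#' @export
print.stationarity_result <- function(x, ...) {
  cat(sprintf("ADF (constant, %d lag(s), n = %d): tau = %.3f, p %s %.3g -> %s\n",
              x$lag_order, x$n_used, x$statistic,
              if (x$p_value <= 0.01) "<=" else if (x$p_value >= 0.99) ">=" else "=",
              x$p_value,
              if (x$passed) "stationary" else "unit root not rejected"))
  invisible(x)
}

#' Average a cohort of activity series on the attachment-offset axis
#'
#' Each cow's series is re-indexed by offset from its own attachment time
#' `t0` (cows attach at different clock times of day), offsets are snapped
#' to the 10-minute grid, and at each offset the mean over the cows with
#' data there is taken. Offsets covered by fewer than `min_frac` of the
#' cows are dropped. The result is an [activity_series()] on the offset
#' axis whose origin (the package reference epoch) plays the role of `t0`.
#'
#' @param series_list List of [activity_series()].
#' @param t0_list Matching vector/list of attachment timestamps.
#' @param min_frac Minimum fraction of cows required at an offset
#'   (default 0.5).
#' @return An [activity_series()] with `cow_id = "cohort"`; its attribute
#'   `t0` holds the offset-axis attachment time.
#' @export
average_cohort <- function(series_list, t0_list, min_frac = 0.5) {
  if (!length(series_list)) stopf("empty cohort")
  if (length(series_list) != length(t0_list))
    stopf("%d series but %d attachment times", length(series_list), length(t0_list))
  n_cows <- length(series_list)
  offs <- lapply(seq_len(n_cows), function(i) {
    s <- series_list[[i]]
    t0 <- as.POSIXct(t0_list[[i]], tz = "UTC")
    off <- round((as.numeric(s$time) - as.numeric(t0)) / .SAMPLE_SEC) * .SAMPLE_SEC
    data.frame(off = off, value = s$values)
  })
  all <- do.call(rbind, offs)
  agg_n <- tapply(all$value, all$off, length)
  agg_m <- tapply(all$value, all$off, mean)
  keep <- agg_n >= min_frac * n_cows
  off_keep <- as.numeric(names(agg_m))[keep]
  o <- order(off_keep)
  t0_axis <- ts_epoch() + 120 * .HOUR  # keep all offsets at positive clock times
  s <- activity_series("cohort", t0_axis + off_keep[o], unname(agg_m[keep][o]))
  attr(s, "t0") <- t0_axis
  s
}
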