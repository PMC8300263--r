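#' Build the analysis window scheme around an attachment time
#'
#' All windows are anchored at `t0`, the moment the calving sensor is
#' attached to the tail, and are half-open `[start, end)`:
#'
#' * `baseline_pre`: `[t0 - 120 h, t0 - 24 h)` -- four-day reference for the
#'   pre-sensor day;
#' * `baseline_post`: `[t0 - 96 h, t0)` -- four-day reference for the
#'   post-sensor day;
#' * `pre_slots`: six 4-hour slots tiling `[t0 - 24 h, t0)`;
#' * `post_slots`: six 4-hour slots tiling `[t0, t0 + 24 h)`;
#' * `video_pre_slots`: three 4-hour slots tiling `[t0 - 24 h, t0 - 12 h)`;
#' * `video_post_slots`: three 4-hour slots tiling `[t0, t0 + 12 h)`.
#'
#' `pre_slots[[i]]` and `post_slots[[i]]` cover the same clock time of day
#' (offset exactly 24 h), so every slot can be compared with a baseline at
#' the same diurnal phase.
#'
#' @param t0 Attachment timestamp (`POSIXct` or anything `as.POSIXct`
#'   accepts; UTC assumed).
#' @return An object of class `window_scheme`.
#' @export
build_window_scheme <- function(t0) {
  t0 <- as.POSIXct(t0, tz = "UTC")
  if (length(t0) != 1L || is.na(t0)) stopf("`t0` must be a single timestamp")
  iv <- function(a, b) c(t0 + a * .HOUR, t0 + b * .HOUR)
  slots <- function(from, n) lapply(seq_len(n) - 1L,
                                    function(i) iv(from + 4 * i, from + 4 * (i + 1)))
  structure(list(
    t0 = t0,
    baseline_pre  = iv(-120, -24),
    baseline_post = iv(-96, 0),
    pre_slots  = slots(-24, 6L),
    post_slots = slots(0, 6L),
    video_pre_slots  = slots(-24, 3L),
    video_post_slots = slots(0, 3L)
  ), class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> t0 = %s UTC\n", format(x$t0, "%Y-%m-%d %H:%M:%S")))
  cat("  baseline_pre  [t0-120h, t0-24h), baseline_post [t0-96h, t0)\n")
  cat("  6 pre slots tiling [t0-24h, t0), 6 post slots tiling [t0, t0+24h)\n")
  cat("  3+3 video slots tiling [t0-24h, t0-12h) and [t0, t0+12h)\n")
  invisible(x)
}

#' Remove the attachment buffer after t0
#'
#' The act of attaching the sensor itself perturbs the first activity
#' reading(s), so every point with timestamp in `[t0, t0 + 10 min)` is
#' dropped. On the device's 10-minute grid this guarantees that the first
#' retained post-attachment point lies 10--15 minutes after `t0` for any
#' phase of `t0` relative to the grid. Points before `t0` are untouched and
#' the operation is idempotent.
#'
#' @param series An [activity_series()].
#' @param t0 Attachment timestamp.
#' @return The buffered [activity_series()]. An empty result is permitted
#'   (with a warning).
#' @export
apply_attachment_buffer <- function(series, t0) {
  stopifnot(inherits(series, "activity_series"))
  if (!length(series$values)) stopf("cow %s: empty series", series$cow_id)
  t0 <- as.POSIXct(t0, tz = "UTC")
  drop <- series$time >= t0 & series$time < t0 + 10 * .MIN
  out <- structure(list(cow_id = series$cow_id, time = series$time[!drop],
                        values = series$values[!drop], interval = series$interval),
                   class = "activity_series")
  if (!length(out$values))
    warning(sprintf("cow %s: attachment buffer removed every point", series$cow_id),
            call. = FALSE)
  out
}

#' Extract the values of a series falling in a half-open window
#'
#' Works on raw [activity_series()] and on detrended series
#' ([first_differences()]). The returned vector carries the observed count
#' and a coverage fraction (observed / expected points at the 10-minute
#' cadence) as attributes, used by the slot-testability rule.
#'
#' @param x An `activity_series` or `detrended_series`.
#' @param interval Length-2 `POSIXct` (or coercible) vector `[start, end)`.
#' @return Numeric vector of values with attributes `n` and `coverage`.
#' @export
slice_window <- function(x, interval) {
  interval <- as.POSIXct(interval, tz = "UTC")
  if (length(interval) != 2L || anyNA(interval) || !(interval[2L] > interval[1L]))
    stopf("`interval` must be a valid [start, end) pair")
  vals <- if (inherits(x, "detrended_series")) x$diffs else x$values
  keep <- x$time >= interval[1L] & x$time < interval[2L]
  out <- vals[keep]
  expected <- max(1, round(as.numeric(interval[2L]) - as.numeric(interval[1L])) / .SAMPLE_SEC)
  attr(out, "n") <- length(out)
  attr(out, "coverage") <- length(out) / expected
  out
}
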