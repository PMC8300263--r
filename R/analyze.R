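#' Per-cow variance-change analysis of the activity index
#'
#' Runs the full activity pipeline for one cow: remove the attachment
#' buffer, detrend the pre-attachment (`t0 - 120 h .. t0`) and
#' post-attachment (`t0 .. t0 + 24 h`) segments separately by first
#' differences, optionally confirm stationarity with the augmented
#' Dickey--Fuller check, then compare the detrended spread of each of the
#' six 4-hour slots of each period with its matching four-day baseline by
#' the Brown--Forsythe test: pre slots against `baseline_pre`
#' (`t0 - 120 .. t0 - 24 h`), post slots against `baseline_post`
#' (`t0 - 96 .. t0`). Slots with detrended coverage below the threshold
#' are flagged untested (never significant). Medians and mean absolute
#' deviations around the median are reported per window on the detrended
#' scale.
#'
#' @param series An [activity_series()] covering `[t0 - 120 h, t0 + 24 h)`
#'   (at least partially).
#' @param t0 Attachment timestamp.
#' @param config List of options: `family_level` (default 0.05),
#'   `slots_per_period` (6; fixes the Bonferroni family), `coverage_min`
#'   (0.5), `run_adf` (`TRUE`), `adf_level` (0.01).
#' @return A `slot_test_table`: data frame with one row per slot (6 pre +
#'   6 post) and columns `cow_id`, `period`, `slot`, `label`, `n_baseline`,
#'   `n_slot`, `coverage`, `median_baseline`, `median_slot`,
#'   `mad_baseline`, `mad_slot`, `W`, `df_within`, `p_value`, `direction`,
#'   `tested`, `significant_raw`, `significant_corrected`. Attributes carry
#'   the resolved config and the stationarity results.
#' @seealso [count_significant()], [analyze_cohort()]
#' @export
analyze_cow <- function(series, t0, config = list()) {
  stopifnot(inherits(series, "activity_series"))
  cfg <- resolve_config(config)
  t0 <- as.POSIXct(t0, tz = "UTC")
  scheme <- build_window_scheme(t0)
  buffered <- apply_attachment_buffer(series, t0)
  pre_seg <- window_series(buffered, c(t0 - 120 * .HOUR, t0))
  post_seg <- window_series(buffered, c(t0, t0 + 24 * .HOUR))
  d_pre <- first_differences(pre_seg, "pre")
  d_post <- first_differences(post_seg, "post")
  adf <- NULL
  if (isTRUE(cfg$run_adf))
    adf <- list(pre = adf_stationarity_check(d_pre, cfg$adf_level),
                post = adf_stationarity_check(d_post, cfg$adf_level))
  base_pre <- slice_window(d_pre, scheme$baseline_pre)
  base_post <- slice_window(d_pre, scheme$baseline_post)
  corrected <- bonferroni_threshold(cfg$family_level, cfg$slots_per_period)
  one_row <- function(period, i, slot_iv, base) {
    vals <- slice_window(if (period == "pre") d_pre else d_post, slot_iv)
    cov <- attr(vals, "coverage")
    tested <- cov >= cfg$coverage_min && length(vals) >= 3L &&
      length(base) >= 3L
    bf <- NULL
    if (tested)
      bf <- tryCatch(brown_forsythe(base, vals), error = function(e) NULL)
    tested <- tested && !is.null(bf)
    data.frame(
      cow_id = series$cow_id, period = period, slot = i,
      label = paste0(period, i),
      n_baseline = length(base), n_slot = length(vals), coverage = cov,
      median_baseline = if (length(base)) median(base) else NA_real_,
      median_slot = if (length(vals)) median(vals) else NA_real_,
      mad_baseline = if (length(base)) mad_around_median(base) else NA_real_,
      mad_slot = if (length(vals)) mad_around_median(vals) else NA_real_,
      W = if (tested) bf$W else NA_real_,
      df_within = if (tested) bf$df_within else NA_integer_,
      p_value = if (tested) bf$p_value else NA_real_,
      direction = if (tested) bf$direction else NA_character_,
      tested = tested,
      significant_raw = tested && bf$p_value < 0.05,
      significant_corrected = tested && bf$p_value < corrected,
      stringsAsFactors = FALSE)
  }
  rows <- c(lapply(1:6, function(i) one_row("pre", i, scheme$pre_slots[[i]], base_pre)),
            lapply(1:6, function(i) one_row("post", i, scheme$post_slots[[i]], base_post)))
  out <- do.call(rbind, rows)
  class(out) <- c("slot_test_table", "data.frame")
  attr(out, "config") <- cfg
  attr(out, "corrected_level") <- corrected
  attr(out, "adf") <- adf
  attr(out, "t0") <- t0
  out
}

resolve_config <- function(config) {
  cfg <- list(family_level = 0.05, slots_per_period = 6L, coverage_min = 0.5,
              run_adf = TRUE, adf_level = 0.01)
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stopf("unknown config option(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

#' Cohort-average variance-change analysis
#'
#' Averages the cohort on the attachment-offset axis with
#' [average_cohort()] (each cow aligned on its own `t0`), then runs
#' [analyze_cow()] on the averaged series with `t0` at offset zero — the
#' averaging-first order means the variability tested is that of the mean
#' activity index across cows.
#'
#' @param series_list List of [activity_series()] (>= 1; a cohort of one
#'   reduces to [analyze_cow()]).
#' @param t0_list Matching attachment timestamps.
#' @param config As in [analyze_cow()].
#' @return A `slot_test_table` with `cow_id = "cohort"`.
#' @export
analyze_cohort <- function(series_list, t0_list, config = list()) {
  avg <- average_cohort(series_list, t0_list)
  analyze_cow(avg, attr(avg, "t0"), config)
}

#' Count significant slots by period and direction
#'
#' The study's headline statistic counts, at the chosen level, how many of
#' the six slots of each period show a significant increase (or decrease)
#' in variability relative to their baseline.
#'
#' @param table A `slot_test_table` from [analyze_cow()]/[analyze_cohort()].
#' @param level `"bonferroni"` (default) or `"raw_0.05"`.
#' @return List of class `significance_counts`: `n_pre_increase`,
#'   `n_post_increase`, `n_pre_decrease`, `n_post_decrease`, `level_used`.
#' @export
count_significant <- function(table, level = c("bonferroni", "raw_0.05")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "slot_test_table"))
  sig <- if (level == "bonferroni") table$significant_corrected
         else table$significant_raw
  sig <- sig & table$tested
  cnt <- function(period, direction)
    sum(sig & table$period == period & table$direction == direction,
        na.rm = TRUE)
  structure(list(n_pre_increase = cnt("pre", "increase"),
                 n_post_increase = cnt("post", "increase"),
                 n_pre_decrease = cnt("pre", "decrease"),
                 n_post_decrease = cnt("post", "decrease"),
                 level_used = level),
            class = "significance_counts")
}

#' @export
print.significance_counts <- function(x, ...) {
  cat(sprintf("significant slots (%s): pre %d increase / %d decrease; post %d increase / %d decrease\n",
              x$level_used, x$n_pre_increase, x$n_pre_decrease,
              x$n_post_increase, x$n_post_decrease))
  invisible(x)
}

#' Post-minus-pre difference in significant-increase slot counts
#'
#' Positive values mean more slots with significantly increased
#' variability after sensor attachment than in the matching pre-sensor
#' period — the pattern expected if the sensor agitates the cow.
#'
#' @param counts A `significance_counts` object.
#' @return Signed integer `n_post_increase - n_pre_increase`.
#' @export
compare_pre_post <- function(counts) {
  stopifnot(inherits(counts, "significance_counts"))
  counts$n_post_increase - counts$n_pre_increase
}

#' Write a slot test table as delimited text
#'
#' Mirrors the published layout: one column per window (the two baselines
#' then the twelve slots) with rows for MAD, median, and the significance
#' mark (`sig.I` / `sig.D` at the corrected level, lower case at the raw
#' level only).
#'
#' @param table A `slot_test_table`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_slot_table <- function(table, path) {
  stopifnot(inherits(table, "slot_test_table"))
  mark <- ifelse(!table$tested, "n.t.",
          ifelse(table$significant_corrected,
                 ifelse(table$direction == "increase", "sig.I", "sig.D"),
          ifelse(table$significant_raw,
                 ifelse(table$direction == "increase", "(sig.I)", "(sig.D)"),
                 "")))
  base_mad <- c(table$mad_baseline[table$label == "pre1"],
                table$mad_baseline[table$label == "post1"])
  base_med <- c(table$median_baseline[table$label == "pre1"],
                table$median_baseline[table$label == "post1"])
  wide <- rbind(MAD = c(round(base_mad, 4), round(table$mad_slot, 4)),
                median = c(round(base_med, 4), round(table$median_slot, 4)),
                brown_forsythe = c("", "", mark))
  colnames(wide) <- c("baseline_pre", "baseline_post", table$label)
  df <- data.frame(quantity = rownames(wide), wide, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
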