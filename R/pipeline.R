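#' Run the full two-approach evaluation end to end
#'
#' Orchestrates both approaches from a single configuration: per-cow and
#' cohort-average variance-change tables, significant-slot counts at raw
#' and Bonferroni-corrected levels, and (when behavioral logs are present)
#' the ethogram slot comparisons for every outcome. Input is either real
#' data (paths to an activity table, an attachment-time table and
#' optionally an event log) or a simulation specification — exactly one of
#' the two.
#'
#' @param config A list with either
#'   * `activity_path`, `attachment_path` (two-column `cow_id`, `t0`
#'     tab-delimited table) and optional `event_log_path`, or
#'   * `simulate = list(n_cows, n_video = 0, events = list(), seed)`;
#'
#'   plus optional analysis options passed to [analyze_cow()]
#'   (`family_level`, `slots_per_period`, `coverage_min`, `run_adf`,
#'   `adf_level`) and `output_dir` for on-disk artifacts.
#' @return List of class `report_bundle`: `per_cow_tables`, `cohort_table`,
#'   `counts` (data frame of significant-slot counts per cow and for the
#'   cohort, at both levels), `ethogram` (per-behavior slot comparisons or
#'   `NULL`), `truth` (simulation ground truth or `NULL`), `run_log`.
#' @export
run_pipeline <- function(config) {
  has_real <- !is.null(config$activity_path) || !is.null(config$attachment_path)
  has_sim <- !is.null(config$simulate)
  if (has_real == has_sim)
    stopf("config must provide exactly one of {activity_path + attachment_path, simulate}")
  ana_cfg <- config[intersect(names(config),
                              c("family_level", "slots_per_period",
                                "coverage_min", "run_adf", "adf_level"))]
  logs <- NULL; truth <- NULL
  if (has_sim) {
    sim <- config$simulate
    if (is.null(sim$n_cows) || is.null(sim$seed))
      stopf("simulation spec needs `n_cows` and `seed`")
    cohort <- simulate_cohort(sim$n_cows,
                              profile_sampler = sim$profile_sampler,
                              event_plan = if (is.null(sim$events)) list() else sim$events,
                              seed = sim$seed,
                              n_video = if (is.null(sim$n_video)) 0 else sim$n_video)
    series_list <- lapply(cohort, `[[`, "series")
    t0_list <- lapply(cohort, `[[`, "t0")
    truth <- lapply(cohort, `[[`, "truth")
    logs <- Filter(Negate(is.null), lapply(cohort, `[[`, "log"))
    names(series_list) <- vapply(series_list, `[[`, character(1), "cow_id")
    if (length(logs)) names(logs) <- vapply(logs, function(l) l$cow_id[1L], character(1))
  } else {
    if (is.null(config$activity_path) || is.null(config$attachment_path))
      stopf("real-data config needs both `activity_path` and `attachment_path`")
    series_list <- read_activity_table(config$activity_path)
    att <- read.delim(config$attachment_path, stringsAsFactors = FALSE)
    if (!all(c("cow_id", "t0") %in% names(att)))
      stopf("attachment table must have columns cow_id, t0")
    missing_t0 <- setdiff(names(series_list), att$cow_id)
    if (length(missing_t0))
      stopf("no attachment time for cow(s): %s", paste(missing_t0, collapse = ", "))
    t0_list <- lapply(names(series_list), function(id)
      as.POSIXct(att$t0[att$cow_id == id][1L], tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")))
    if (!is.null(config$event_log_path))
      logs <- read_event_log(config$event_log_path)
  }
  per_cow <- lapply(seq_along(series_list), function(i)
    analyze_cow(series_list[[i]], t0_list[[i]], ana_cfg))
  names(per_cow) <- names(series_list)
  cohort_table <- if (length(series_list) >= 2L)
    analyze_cohort(series_list, t0_list, ana_cfg) else per_cow[[1L]]
  count_row <- function(tab, who) {
    cb <- count_significant(tab, "bonferroni")
    cr <- count_significant(tab, "raw_0.05")
    data.frame(cow_id = who,
               pre_increase_corrected = cb$n_pre_increase,
               post_increase_corrected = cb$n_post_increase,
               pre_decrease_corrected = cb$n_pre_decrease,
               post_decrease_corrected = cb$n_post_decrease,
               post_minus_pre_corrected = compare_pre_post(cb),
               pre_increase_raw = cr$n_pre_increase,
               post_increase_raw = cr$n_post_increase,
               post_minus_pre_raw = compare_pre_post(cr),
               stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, c(lapply(names(per_cow),
                                    function(id) count_row(per_cow[[id]], id)),
                             list(count_row(cohort_table, "cohort"))))
  etho <- NULL
  if (!is.null(logs) && length(logs) >= 2L) {
    schemes <- lapply(names(logs), function(id) {
      i <- match(id, names(series_list))
      build_window_scheme(t0_list[[i]])
    })
    names(schemes) <- names(logs)
    outcomes <- c("walking", "standing", "lying", "eating", "drinking",
                  "rubbing_tail", "social_interaction", "tail_raising",
                  "standing_bouts", "lying_bouts")
    etho <- do.call(rbind, lapply(outcomes, function(b)
      compare_slot_pairs(logs, schemes, b)))
  }
  run_log <- list(
    n_cows = length(series_list),
    n_logs = if (is.null(logs)) 0L else length(logs),
    config = attr(per_cow[[1L]], "config"),
    corrected_level = attr(per_cow[[1L]], "corrected_level"),
    buffer = "drop points in [t0, t0 + 10 min)",
    detrending = "first differences per segment (pre, post); no difference across t0",
    adf_rule = "constant, no trend; lag = floor((n-1)^(1/3))",
    direction_tie_rule = "MAD tie labelled decrease",
    median_rule = "even-sized median = midpoint of central order statistics")
  bundle <- structure(list(per_cow_tables = per_cow, cohort_table = cohort_table,
                           counts = counts, ethogram = etho, truth = truth,
                           run_log = run_log),
                      class = "report_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d cow(s), %d behavioral log(s)\n",
              x$run_log$n_cows, x$run_log$n_logs))
  cat("cohort significant-slot counts:\n")
  print(x$counts[x$counts$cow_id == "cohort", , drop = FALSE], row.names = FALSE)
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(bundle$per_cow_tables))
    write_slot_table(bundle$per_cow_tables[[id]],
                     file.path(dir, paste0("slot_table_", id, ".tsv")))
  write_slot_table(bundle$cohort_table, file.path(dir, "slot_table_cohort.tsv"))
  write.table(bundle$counts, file.path(dir, "significant_slot_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$ethogram))
    write.table(bundle$ethogram, file.path(dir, "ethogram_comparisons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$run_log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Calibration and power study of the slot variance procedure
#'
#' Simulates `n_replicates` independent cows under a common event plan and
#' runs the per-cow pipeline on each, returning empirical per-slot
#' rejection rates at the raw and Bonferroni-corrected levels with
#' binomial standard errors, the per-period family-wise rejection rate at
#' the corrected level, and — when the event plan injects variance shifts —
#' the corrected-level recovery rate of the truly shifted slots.
#'
#' @param config List: `seed` (required), optional `events` (list of
#'   [variance_event()]s applied to every replicate), `profile` (a
#'   [cow_profile()]; default standard), plus [analyze_cow()] options.
#' @param n_replicates Number of simulated cows (>= 100 recommended; fewer
#'   draws a warning).
#' @return List of class `calibration_summary`: `n_replicates`, `per_slot`
#'   (data frame: label, raw/corrected rejection rates in either direction
#'   plus the corrected increase-direction rate, with binomial SEs),
#'   `fwer_corrected` (pre, post), `shifted_slots`, `recovery_corrected`
#'   (corrected-level increase-direction rate over the truly shifted
#'   slots, `NA` if none), `null_raw_rate` (pooled raw rate over
#'   unshifted slots).
#' @export
run_calibration <- function(config, n_replicates) {
  if (is.null(config$seed)) stopf("calibration config needs `seed`")
  if (n_replicates < 100)
    warning("fewer than 100 replicates: rates will be noisy", call. = FALSE)
  events <- if (is.null(config$events)) list() else config$events
  profile <- if (is.null(config$profile)) cow_profile() else config$profile
  ana_cfg <- config[intersect(names(config),
                              c("family_level", "slots_per_period",
                                "coverage_min", "run_adf", "adf_level"))]
  if (is.null(ana_cfg$run_adf)) ana_cfg$run_adf <- FALSE  # speed: checked once below
  t0 <- ts_epoch() + 120 * .HOUR
  labels <- c(paste0("pre", 1:6), paste0("post", 1:6))
  shifted <- shifted_slot_labels(events)
  raw <- corr <- corr_inc <- matrix(NA, n_replicates, 12L,
                                    dimnames = list(NULL, labels))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_activity_series(profile, t0, 120, 24, events = events,
                                    seed = split_seed(config$seed, r))
    cfg_r <- ana_cfg
    if (r == 1L) cfg_r$run_adf <- TRUE  # stationarity confirmed on the first draw
    tab <- analyze_cow(sim$series, t0, cfg_r)
    raw[r, tab$label] <- tab$significant_raw
    corr[r, tab$label] <- tab$significant_corrected
    corr_inc[r, tab$label] <- tab$significant_corrected & tab$direction == "increase"
  }
  per_slot <- data.frame(
    label = labels,
    raw_rate = colMeans(raw, na.rm = TRUE),
    corrected_rate = colMeans(corr, na.rm = TRUE),
    corrected_increase_rate = colMeans(corr_inc, na.rm = TRUE),
    stringsAsFactors = FALSE)
  per_slot$raw_se <- sqrt(per_slot$raw_rate * (1 - per_slot$raw_rate) / n_replicates)
  per_slot$corrected_se <- sqrt(per_slot$corrected_rate * (1 - per_slot$corrected_rate) / n_replicates)
  pre_cols <- grepl("^pre", labels); post_cols <- !pre_cols
  fwer <- c(pre = mean(apply(corr[, pre_cols, drop = FALSE], 1L, any, na.rm = TRUE)),
            post = mean(apply(corr[, post_cols, drop = FALSE], 1L, any, na.rm = TRUE)))
  null_cols <- setdiff(labels, shifted)
  structure(list(
    n_replicates = n_replicates,
    per_slot = per_slot,
    fwer_corrected = fwer,
    shifted_slots = shifted,
    recovery_corrected = if (length(shifted))
      mean(corr_inc[, shifted, drop = FALSE], na.rm = TRUE) else NA_real_,
    null_raw_rate = mean(raw[, null_cols, drop = FALSE], na.rm = TRUE)),
    class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat(sprintf("<calibration_summary> %d replicates\n", x$n_replicates))
  cat(sprintf("pooled raw rejection rate over null slots: %.4f\n",
              x$null_raw_rate))
  cat(sprintf("corrected-level FWER: pre %.4f, post %.4f\n",
              x$fwer_corrected["pre"], x$fwer_corrected["post"]))
  if (length(x$shifted_slots))
    cat(sprintf("recovery of shifted slot(s) [%s] at corrected level: %.3f\n",
                paste(x$shifted_slots, collapse = ", "), x$recovery_corrected))
  invisible(x)
}

#' Percentage of attached devices that failed to stay on the tail
#'
#' Simple retention arithmetic used when reporting device performance:
#' e.g. 4 of 36 adhesive-mounted devices falling off is 11.1%, and 23 of
#' 37 ratchet-mounted devices not remaining on the tail is 62.2%.
#'
#' @param n_failed Number of devices that fell off / were removed.
#' @param n_attached Total number of devices attached (> 0).
#' @return Percentage `100 * n_failed / n_attached`.
#' @export
attachment_failure_percent <- function(n_failed, n_attached) {
  if (!is_scalar_num(n_attached) || n_attached <= 0)
    stopf("`n_attached` must be > 0")
  if (!is_scalar_num(n_failed) || n_failed < 0 || n_failed > n_attached)
    stopf("`n_failed` must lie in [0, n_attached]")
  100 * n_failed / n_attached
}
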