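.STATE_BEHAVIORS <- c("walking", "standing", "lying", "eating", "drinking")
.POINT_BEHAVIORS <- "tail_raising"
.INTERVAL_BEHAVIORS <- c("rubbing_tail", "social_interaction")
.SOCIAL_SUBTYPES <- c("social_licking", "sniffing_head", "sniffing_body",
                      "gentle_pushing", "head_butting", "fighting")

as_event_log <- function(df) {
  class(df) <- c("event_log", "data.frame")
  df
}

#' Validate a behavioral event log against the closed ethogram
#'
#' Checks that every record uses a known behavior label; that the five
#' primary state behaviors are non-overlapping and gap-free (they tile the
#' coded span); that tail raises are end-free point events (the lateral
#' > 90 degree definition is observational metadata, not computed here);
#' that interval behaviors have `end > start`; and that every
#' social-interaction interval carries exactly one known subtype. Records
#' are returned sorted by start time.
#'
#' @param log A data.frame (or `event_log`) with columns `cow_id`,
#'   `behavior`, `subtype`, `start`, `end` (`NA` end for point events).
#' @param tol Tolerance in seconds for gap/overlap detection between
#'   consecutive state records (default 1 s, the timestamp resolution).
#' @return The validated, sorted `event_log`.
#' @export
validate_event_log <- function(log, tol = 1) {
  if (!is.data.frame(log)) stopf("`log` must be a data.frame of event records")
  need <- c("cow_id", "behavior", "start")
  if (!all(need %in% names(log)))
    stopf("event log must have columns %s", paste(need, collapse = ", "))
  if (!"subtype" %in% names(log)) log$subtype <- NA_character_
  if (!"end" %in% names(log)) log$end <- as.POSIXct(NA)
  parse_ts <- function(x) {
    if (is.character(x) || is.factor(x)) {
      out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
      ok <- !is.na(x) & nzchar(x)
      if (any(ok))
        out[ok] <- as.POSIXct(x[ok], tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%d %H:%M:%OS"))
      out
    } else as.POSIXct(x, tz = "UTC")
  }
  log$start <- parse_ts(log$start)
  log$end <- parse_ts(log$end)
  if (anyNA(log$start)) stopf("unparsable start timestamp(s) in event log")
  known <- c(.STATE_BEHAVIORS, .POINT_BEHAVIORS, .INTERVAL_BEHAVIORS)
  bad <- !log$behavior %in% known
  if (any(bad))
    stopf("unknown behavior label(s): %s (closed ethogram)",
          paste(unique(log$behavior[bad]), collapse = ", "))
  log <- log[order(log$start), , drop = FALSE]
  rownames(log) <- NULL
  pt <- log$behavior %in% .POINT_BEHAVIORS
  if (any(pt & !is.na(log$end)))
    stopf("point events (tail_raising) must have no end timestamp")
  iv <- log$behavior %in% c(.STATE_BEHAVIORS, .INTERVAL_BEHAVIORS)
  if (any(iv & (is.na(log$end) | log$end <= log$start)))
    stopf("state/interval records must have end > start")
  soc <- log$behavior == "social_interaction"
  if (any(soc & (is.na(log$subtype) | !log$subtype %in% .SOCIAL_SUBTYPES)))
    stopf("every social_interaction interval needs exactly one known subtype")
  st <- log[log$behavior %in% .STATE_BEHAVIORS, , drop = FALSE]
  if (nrow(st) > 1L) {
    jump <- as.numeric(st$start[-1L]) - as.numeric(st$end[-nrow(st)])
    off <- which(abs(jump) > tol)
    if (length(off)) {
      i <- off[1L]
      stopf("primary states must tile the coded span: %s at %s (%+.0f s) between records %d and %d",
            if (jump[i] > 0) "gap" else "overlap",
            format(st$end[i], "%Y-%m-%d %H:%M:%S"), jump[i], i, i + 1L)
    }
  }
  as_event_log(log)
}

#' Read / write behavioral event logs
#'
#' Tab-delimited schema: `cow_id`, `behavior`, `subtype` (empty for none),
#' `start` (ISO-8601 UTC), `end` (empty for point events).
#'
#' @param path File path.
#' @return `read_event_log()`: a named list of validated `event_log`s, one
#'   per cow. `write_event_log()`: `path`, invisibly.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stopf("event log not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  out <- lapply(split(df, df$cow_id), validate_event_log)
  out[unique(df$cow_id)]
}

#' @rdname read_event_log
#' @param logs One `event_log` or a list of them.
#' @export
write_event_log <- function(logs, path) {
  if (is.data.frame(logs)) logs <- list(logs)
  df <- do.call(rbind, lapply(logs, as.data.frame))
  df$start <- format(df$start, "%Y-%m-%dT%H:%M:%S")
  df$end <- ifelse(is.na(df$end), "", format(df$end, "%Y-%m-%dT%H:%M:%S"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# total minutes of `behavior` records clipped to [slot_start, slot_end)
clipped_minutes <- function(log, behavior, slot) {
  r <- log[log$behavior == behavior & !is.na(log$end), , drop = FALSE]
  if (!nrow(r)) return(0)
  a <- pmax(as.numeric(r$start), as.numeric(slot[1L]))
  b <- pmin(as.numeric(r$end), as.numeric(slot[2L]))
  sum(pmax(0, b - a)) / .MIN
}

#' Summarise coded behavior within one time slot
#'
#' Clips every record to the half-open slot, accumulates durations in
#' minutes for the five primary states and the two parallel interval
#' behaviors, counts tail raises whose timestamp falls in the slot, counts
#' standing and lying bouts (see [count_bouts()]) and reports the time
#' proportions of the five primary behaviors.
#'
#' @param log A validated `event_log` for one cow.
#' @param slot Length-2 `POSIXct` interval `[start, end)`; must lie inside
#'   the coded span of the log.
#' @return List of class `slot_behavior_summary` with elements `cow_id`,
#'   `slot`, `duration_minutes` (named vector), `tail_raise_count`,
#'   `standing_bouts`, `lying_bouts`, `proportions`.
#' @export
slot_summary <- function(log, slot) {
  stopifnot(is.data.frame(log))
  slot <- as.POSIXct(slot, tz = "UTC")
  st <- log[log$behavior %in% .STATE_BEHAVIORS, , drop = FALSE]
  if (!nrow(st)) stopf("log has no primary-state records")
  if (slot[1L] < min(st$start) - 1 || slot[2L] > max(st$end) + 1)
    stopf("slot [%s, %s) lies outside the coded span [%s, %s)",
          format(slot[1L]), format(slot[2L]),
          format(min(st$start)), format(max(st$end)))
  dur <- vapply(c(.STATE_BEHAVIORS, .INTERVAL_BEHAVIORS),
                clipped_minutes, numeric(1), log = log, slot = slot)
  tr <- log$behavior == "tail_raising" &
    log$start >= slot[1L] & log$start < slot[2L]
  prim <- dur[.STATE_BEHAVIORS]
  bouts <- count_bouts(log, slot)
  structure(list(cow_id = log$cow_id[1L], slot = slot,
                 duration_minutes = dur,
                 tail_raise_count = sum(tr),
                 standing_bouts = bouts[["standing_bouts"]],
                 lying_bouts = bouts[["lying_bouts"]],
                 proportions = prim / sum(prim)),
            class = "slot_behavior_summary")
}

#' @export
print.slot_behavior_summary <- function(x, ...) {
  cat(sprintf("<slot_behavior_summary> cow %s, slot %s .. %s\n", x$cow_id,
              format(x$slot[1L], "%H:%M"), format(x$slot[2L], "%H:%M")))
  print(round(x$duration_minutes, 1))
  cat(sprintf("tail raises: %d, standing bouts: %d, lying bouts: %d\n",
              x$tail_raise_count, x$standing_bouts, x$lying_bouts))
  invisible(x)
}

#' Count standing and lying bouts within a slot
#'
#' Eating and drinking take place while standing and are therefore counted
#' as "standing" when determining bout numbers. Walking remains its own
#' state and terminates both standing and lying bouts (a
#' lying-walking-lying sequence yields two lying bouts and no standing
#' bout). A bout is a maximal unbroken run of one mapped posture; a bout in
#' progress at the slot start counts in this slot, making the count
#' invariant to splitting any record into adjacent same-state records.
#'
#' @param log A validated `event_log`.
#' @param slot Length-2 interval `[start, end)`.
#' @return Named integer vector `c(standing_bouts = , lying_bouts = )`.
#' @export
count_bouts <- function(log, slot) {
  slot <- as.POSIXct(slot, tz = "UTC")
  st <- log[log$behavior %in% .STATE_BEHAVIORS, , drop = FALSE]
  st <- st[st$end > slot[1L] & st$start < slot[2L], , drop = FALSE]
  if (!nrow(st)) return(c(standing_bouts = 0L, lying_bouts = 0L))
  st <- st[order(st$start), , drop = FALSE]
  posture <- ifelse(st$behavior %in% c("standing", "eating", "drinking"),
                    "standing", st$behavior)
  runs <- rle(posture)$values
  c(standing_bouts = sum(runs == "standing"), lying_bouts = sum(runs == "lying"))
}

#' Paired Wilcoxon signed-rank test with continuity correction
#'
#' Compares matched per-cow slot statistics before and after sensor
#' attachment. Differences `post - pre` are formed, zero differences are
#' dropped (standard signed-rank convention), tied absolute differences
#' receive mid-ranks, and the two-sided p-value comes from the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction (delegated to [stats::wilcox.test()]). If every difference
#' is zero the result is flagged degenerate with `p = 1`.
#'
#' @param pre_values,post_values Matching numeric vectors (one entry per
#'   cow), length >= 2.
#' @return List of class `paired_test_result`: `statistic` (sum of positive
#'   ranks), `p_value`, `n_pairs`, `n_nonzero`, `medians` (pre, post),
#'   `mads` (pre, post; mean absolute deviation around the median),
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values))
    stopf("pre and post vectors must have equal length")
  if (length(pre_values) < 2L) stopf("need at least 2 pairs")
  ok <- complete.cases(pre_values, post_values)
  pre <- pre_values[ok]; post <- post_values[ok]
  d <- post - pre
  nz <- d != 0
  base <- list(n_pairs = length(d), n_nonzero = sum(nz),
               medians = c(pre = median(pre), post = median(post)),
               mads = c(pre = mad_around_median(pre),
                        post = mad_around_median(post)))
  if (!any(nz)) {
    return(structure(c(list(statistic = 0, p_value = 1, degenerate = TRUE), base),
                     class = "paired_test_result"))
  }
  ht <- suppressWarnings(
    wilcox.test(post[nz], pre[nz], paired = TRUE, exact = FALSE,
                correct = TRUE))
  structure(c(list(statistic = unname(ht$statistic),
                   p_value = ht$p.value, degenerate = FALSE), base),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank (cc): V = %g, p = %.4g (n = %d, nonzero = %d)%s\n",
              x$statistic, x$p_value, x$n_pairs, x$n_nonzero,
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  cat(sprintf("medians pre/post: %.3g / %.3g, MADs: %.3g / %.3g\n",
              x$medians[1L], x$medians[2L], x$mads[1L], x$mads[2L]))
  invisible(x)
}

# the per-slot outcome extracted for a behavior
slot_outcome <- function(summary, behavior) {
  switch(behavior,
         tail_raising = summary$tail_raise_count,
         standing_bouts = summary$standing_bouts,
         lying_bouts = summary$lying_bouts,
         summary$duration_minutes[[behavior]])
}

#' Compare paired pre/post video slots across the cohort
#'
#' For each of the three video slot indices, the per-cow outcome (duration
#' in minutes for duration behaviors, count for `tail_raising`,
#' `standing_bouts` and `lying_bouts`) is computed in the pre-sensor slot
#' (same clock time the day before) and the post-sensor slot, and the pairs
#' are tested with [wilcoxon_signed_rank()]. Cows whose log does not cover
#' both windows are excluded with a warning.
#'
#' @param logs Named list of validated `event_log`s (one per cow).
#' @param schemes Matching named list of [build_window_scheme()] objects.
#' @param behavior One of the duration behaviors (`walking`, `standing`,
#'   `lying`, `eating`, `drinking`, `rubbing_tail`, `social_interaction`),
#'   `tail_raising`, `standing_bouts` or `lying_bouts`.
#' @return Data frame of class `slot_pair_results` with one row per slot
#'   index: `behavior`, `slot_index`, `statistic`, `p_value`, `n_pairs`,
#'   `n_nonzero`, `median_pre`, `median_post`, `mad_pre`, `mad_post`,
#'   `degenerate`.
#' @export
compare_slot_pairs <- function(logs, schemes, behavior) {
  ok_behaviors <- c(.STATE_BEHAVIORS, .INTERVAL_BEHAVIORS, "tail_raising",
                    "standing_bouts", "lying_bouts")
  if (!behavior %in% ok_behaviors)
    stopf("`behavior` must be one of: %s", paste(ok_behaviors, collapse = ", "))
  if (length(logs) != length(schemes))
    stopf("%d logs but %d window schemes", length(logs), length(schemes))
  ids <- names(logs)
  if (is.null(ids)) ids <- as.character(seq_along(logs))
  usable <- vapply(seq_along(logs), function(i) {
    st <- logs[[i]][logs[[i]]$behavior %in% .STATE_BEHAVIORS, , drop = FALSE]
    sch <- schemes[[i]]
    cover <- min(st$start) <= sch$video_pre_slots[[1L]][1L] + 1 &&
      max(st$end) >= sch$video_post_slots[[3L]][2L] - 1
    cover
  }, logical(1))
  if (!all(usable))
    warning(sprintf("excluding %d cow(s) without both video windows coded: %s",
                    sum(!usable), paste(ids[!usable], collapse = ", ")),
            call. = FALSE)
  logs <- logs[usable]; schemes <- schemes[usable]
  rows <- lapply(1:3, function(i) {
    pre <- vapply(seq_along(logs), function(j)
      slot_outcome(slot_summary(logs[[j]], schemes[[j]]$video_pre_slots[[i]]),
                   behavior), numeric(1))
    post <- vapply(seq_along(logs), function(j)
      slot_outcome(slot_summary(logs[[j]], schemes[[j]]$video_post_slots[[i]]),
                   behavior), numeric(1))
    r <- wilcoxon_signed_rank(pre, post)
    data.frame(behavior = behavior, slot_index = i,
               statistic = r$statistic, p_value = r$p_value,
               n_pairs = r$n_pairs, n_nonzero = r$n_nonzero,
               median_pre = r$medians[["pre"]], median_post = r$medians[["post"]],
               mad_pre = r$mads[["pre"]], mad_post = r$mads[["post"]],
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("slot_pair_results", "data.frame")
  out
}

#' Leave-one-cow-out sensitivity re-test
#'
#' Repeats [compare_slot_pairs()] with one cow removed, the standard probe
#' for results driven by a single animal.
#'
#' @inheritParams compare_slot_pairs
#' @param cow_id Name of the cow to drop (must be present in `logs`).
#' @return As [compare_slot_pairs()], computed on the remaining cows.
#' @export
sensitivity_drop_cow <- function(logs, schemes, behavior, cow_id) {
  ids <- names(logs)
  if (is.null(ids) || !cow_id %in% ids)
    stopf("unknown cow_id '%s'", cow_id)
  keep <- ids != cow_id
  compare_slot_pairs(logs[keep], schemes[keep], behavior)
}
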