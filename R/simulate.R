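#' Simulate one cow's activity-index series with known ground truth
#'
#' Generates a 10-minute-cadence activity-index stream following the
#' [cow_profile()] model: diurnal sinusoid plus AR(1) noise, clamped to
#' \[1, 100\]. Inside any [variance_event()] the AR(1) innovation standard
#' deviation is multiplied by the event's inflation factor, encoding a
#' genuine change in short-term variability of activity. Points are then
#' dropped independently at the profile's `missing_rate`. Identical
#' `(profile, events, seed)` give bit-identical output.
#'
#' @param profile A [cow_profile()].
#' @param t0 Attachment timestamp (`POSIXct` or coercible; UTC).
#' @param span_before,span_after Hours simulated before/after `t0`. For the
#'   full analysis pipeline use at least 120 h before and 24 h after.
#' @param events List of [variance_event()]s (possibly empty).
#' @param seed Integer seed (required for reproducibility).
#' @return List with elements `series` (an [activity_series()]) and `truth`
#'   (class `sim_truth`: `cow_id`, `shifted_slots`, `events`, `t0`).
#' @examples
#' sim <- simulate_activity_series(cow_profile("c1"), "2018-08-01 10:00:00",
#'                                 events = list(variance_event(4, 4, 3)),
#'                                 seed = 1)
#' sim$truth$shifted_slots  # "post2"
#' @export
simulate_activity_series <- function(profile, t0,
                                     span_before = 120, span_after = 24,
                                     events = list(), seed) {
  stopifnot(inherits(profile, "cow_profile"))
  if (missing(seed)) stopf("`seed` is required")
  if (!is_scalar_num(span_before) || !is_scalar_num(span_after) ||
      span_before <= 0 || span_after <= 0)
    stopf("`span_before` and `span_after` must be positive hour counts")
  if (inherits(events, "variance_event")) events <- list(events)
  if (!all(vapply(events, inherits, logical(1), "variance_event")))
    stopf("`events` must be a list of variance_event objects")
  t0 <- as.POSIXct(t0, tz = "UTC")
  n <- round(6 * (span_before + span_after))
  off <- (seq_len(n) - 1L) * .SAMPLE_SEC - span_before * .HOUR  # seconds from t0
  tm <- t0 + off
  # innovation scale, inflated where an event covers the timestamp
  sd_t <- rep(profile$noise_sd, n)
  for (ev in events) {
    a <- ev$start_offset * .HOUR
    b <- a + ev$duration * .HOUR
    sd_t[off >= a & off < b] <- profile$noise_sd * ev$inflation_factor
  }
  with_seed(seed, {
    innov <- rnorm(n) * sd_t
    ar <- if (profile$ar_coefficient != 0)
      as.numeric(filter(innov, profile$ar_coefficient, method = "recursive"))
    else innov
    hour_of_day <- (as.numeric(tm) %% 86400) / .HOUR
    x <- profile$base_level +
      profile$diurnal_amplitude * cos(2 * pi * (hour_of_day - profile$diurnal_phase) / 24) +
      ar
    x <- pmin(100, pmax(1, x))
    keep <- if (profile$missing_rate > 0) runif(n) >= profile$missing_rate
            else rep(TRUE, n)
    series <- activity_series(profile$cow_id, tm[keep], x[keep])
    truth <- structure(list(cow_id = profile$cow_id,
                            shifted_slots = shifted_slot_labels(events),
                            events = events, t0 = t0),
                       class = "sim_truth")
    list(series = series, truth = truth)
  })
}

#' Simulate a behavioral event log
#'
#' Generates a coded observation log over `[t_start, t_start + span)`:
#' a semi-Markov sequence over the five state behaviors (exponential dwell
#' times at the repertoire's mean dwell, next state by transition weights,
#' self-transitions excluded) that exactly tiles the span; tail raises as a
#' Poisson point process; tail rubbing and social interaction as
#' Poisson-started intervals with exponential lengths (clipped to the
#' span), each social interval carrying exactly one subtype.
#'
#' @param repertoire A [behavior_repertoire()].
#' @param t_start Start of the coded span (`POSIXct` or coercible; UTC).
#' @param span Coded span in hours, > 0.
#' @param seed Integer seed.
#' @param cow_id Identifier recorded on the log.
#' @return An `event_log` (see [validate_event_log()]).
#' @export
simulate_ethogram <- function(repertoire, t_start, span, seed, cow_id = "cow1") {
  stopifnot(inherits(repertoire, "behavior_repertoire"))
  if (!is_scalar_num(span) || span <= 0) stopf("`span` must be > 0 hours")
  if (missing(seed)) stopf("`seed` is required")
  t_start <- as.POSIXct(t_start, tz = "UTC")
  t_end <- t_start + span * .HOUR
  states <- repertoire$state_behaviors
  dwell_sec <- repertoire$mean_dwell[states] * .MIN
  tw <- repertoire$transition_weights
  with_seed(seed, {
    # time-weighted initial state: dwell-proportional start is the natural
    # stationary-ish choice for a log that opens mid-stream
    cur <- sample(states, 1L, prob = dwell_sec / sum(dwell_sec))
    bnd <- as.numeric(t_start); labs <- character(0)
    now <- as.numeric(t_start)
    end_n <- as.numeric(t_end)
    while (now < end_n) {
      d <- rexp(1L, rate = 1 / dwell_sec[[cur]])
      now <- min(now + d, end_n)
      bnd <- c(bnd, now); labs <- c(labs, cur)
      cur <- sample(states, 1L, prob = tw[cur, ])
    }
    # timestamps live on a 1-second grid; rounding the segment boundaries
    # keeps the tiling exact, zero-length segments are dropped
    bnd <- round(bnd)
    keep <- diff(bnd) > 0
    starts <- bnd[-length(bnd)][keep]
    ends <- bnd[-1L][keep]
    labs <- labs[keep]
    recs <- data.frame(cow_id = cow_id, behavior = labs, subtype = NA_character_,
                       start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
                       end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"),
                       stringsAsFactors = FALSE)
    pois_times <- function(rate) {
      k <- rpois(1L, rate * span)
      round(sort(runif(k, as.numeric(t_start), end_n)))
    }
    tr <- pois_times(repertoire$tail_raise_rate)
    if (length(tr))
      recs <- rbind(recs, data.frame(
        cow_id = cow_id, behavior = "tail_raising", subtype = NA_character_,
        start = as.POSIXct(tr, origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(NA), stringsAsFactors = FALSE))
    add_intervals <- function(recs, behavior, rate, subtypes = NULL) {
      st <- pois_times(rate)
      if (!length(st)) return(recs)
      len <- rexp(length(st), rate = 1 / (repertoire$mean_dwell[[behavior]] * .MIN))
      en <- round(pmin(st + len, end_n))
      ok <- en > st
      if (!any(ok)) return(recs)
      sub <- if (is.null(subtypes)) NA_character_
             else sample(names(subtypes), sum(ok), replace = TRUE,
                         prob = subtypes / sum(subtypes))
      rbind(recs, data.frame(
        cow_id = cow_id, behavior = behavior, subtype = sub,
        start = as.POSIXct(st[ok], origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(en[ok], origin = "1970-01-01", tz = "UTC"),
        stringsAsFactors = FALSE))
    }
    recs <- add_intervals(recs, "rubbing_tail", repertoire$rubbing_rate)
    recs <- add_intervals(recs, "social_interaction", repertoire$social_rate,
                          repertoire$subtype_weights)
    validate_event_log(as_event_log(recs))
  })
}

#' Simulate a cohort of cows with activity series and event logs
#'
#' Draws `n_cows` independent cows. Each cow receives its own seed (split
#' deterministically from the cohort seed) and an attachment time `t0` at a
#' distinct clock time of day on the 10-minute grid, reproducing the
#' per-cow time-of-day heterogeneity of attachment in practice. Event logs
#' (36 h spanning `t0 - 24 h .. t0 + 12 h`, covering both video windows)
#' are generated for the first `n_video` cows.
#'
#' @param n_cows Number of cows, >= 1.
#' @param profile_sampler Function `(cow_id) -> cow_profile`; defaults to
#'   the standard profile for every cow.
#' @param event_plan Either a single list of [variance_event()]s applied to
#'   every cow, or a list of such lists (one per cow).
#' @param seed Cohort seed.
#' @param n_video Number of cows (from the first) that also get an event
#'   log; default 0.
#' @param repertoire [behavior_repertoire()] used for the logs.
#' @param base_date Calendar date on which attachment days fall.
#' @return List with one element per cow: `series`, `truth`, `t0`, and
#'   `log` (`NULL` when not simulated).
#' @export
simulate_cohort <- function(n_cows, profile_sampler = NULL, event_plan = list(),
                            seed, n_video = 0,
                            repertoire = behavior_repertoire(),
                            base_date = "2018-08-01") {
  if (!is_scalar_num(n_cows) || n_cows < 1) stopf("`n_cows` must be >= 1")
  if (missing(seed)) stopf("`seed` is required")
  n_cows <- as.integer(n_cows)
  if (is.null(profile_sampler))
    profile_sampler <- function(cow_id) cow_profile(cow_id)
  per_cow_events <- if (length(event_plan) && inherits(event_plan[[1L]], "variance_event"))
    rep(list(event_plan), n_cows)
  else if (length(event_plan)) {
    if (length(event_plan) != n_cows)
      stopf("`event_plan` has %d entries for %d cows", length(event_plan), n_cows)
    event_plan
  } else rep(list(list()), n_cows)
  day0 <- as.POSIXct(paste(base_date, "00:00:00"), tz = "UTC")
  # distinct clock times of day on the 10-minute grid
  slots_of_day <- with_seed(split_seed(seed, 0L),
                            sample(seq(0L, 143L), n_cows, replace = n_cows > 144))
  lapply(seq_len(n_cows), function(i) {
    prof <- profile_sampler(paste0("cow", i))
    stopifnot(inherits(prof, "cow_profile"))
    t0 <- day0 + 120 * .HOUR + slots_of_day[i] * .SAMPLE_SEC
    sim <- simulate_activity_series(prof, t0, 120, 24,
                                    events = per_cow_events[[i]],
                                    seed = split_seed(seed, i))
    log <- NULL
    if (i <= n_video)
      log <- simulate_ethogram(repertoire, t0 - 24 * .HOUR, 36,
                               seed = split_seed(seed, n_cows + i),
                               cow_id = prof$cow_id)
    list(series = sim$series, truth = sim$truth, t0 = t0, log = log)
  })
}

#' Write simulation ground truth as JSON
#'
#' Serializes one or more `sim_truth` objects (which slots overlap a
#' variance-inflation event, and the raw event list) to a structured-text
#' sidecar next to the simulated activity fixtures.
#'
#' @param truths A `sim_truth` or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truths, path) {
  if (inherits(truths, "sim_truth")) truths <- list(truths)
  payload <- lapply(truths, function(tr) list(
    cow_id = tr$cow_id,
    t0 = format(tr$t0, "%Y-%m-%dT%H:%M:%S"),
    shifted_slots = as.list(tr$shifted_slots),
    events = lapply(tr$events, function(ev)
      list(start_offset = ev$start_offset, duration = ev$duration,
           inflation_factor = ev$inflation_factor))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
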