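#' Generative profile of one cow's activity-index stream
#'
#' Describes the clamped diurnal-sinusoid + AR(1) model used by
#' [simulate_activity_series()]: the simulated index at time `t` is
#' `base_level + diurnal_amplitude * cos(2*pi*(h(t) - diurnal_phase)/24) + e(t)`
#' clamped to \[1, 100\], where `h(t)` is the clock hour and `e(t)` is an
#' AR(1) process with coefficient `ar_coefficient` and innovation standard
#' deviation `noise_sd` (inflated inside any active [variance_event()]).
#'
#' The defaults are the package's study conditions: a mid-scale mean level
#' (30) with a visible diurnal rhythm (amplitude 10 peaking mid-afternoon)
#' and strongly persistent noise (AR coefficient 0.7, innovation SD 4),
#' reflecting that behavioral bouts span many 10-minute sampling intervals.
#'
#' @param cow_id Identifier.
#' @param base_level Target mean level, in activity-index units in \[1, 100\].
#' @param diurnal_amplitude Amplitude of the 24-h sinusoid (same units, >= 0).
#' @param diurnal_phase Clock hour of peak activity, in \[0, 24).
#' @param ar_coefficient AR(1) coefficient in (-1, 1).
#' @param noise_sd Innovation standard deviation, > 0 (0 permitted for the
#'   degenerate noise-free case).
#' @param missing_rate Probability in \[0, 1) that any point is dropped.
#' @return List of class `cow_profile`.
#' @export
cow_profile <- function(cow_id = "cow1", base_level = 30,
                        diurnal_amplitude = 10, diurnal_phase = 14,
                        ar_coefficient = 0.7, noise_sd = 4,
                        missing_rate = 0) {
  if (!is_scalar_num(base_level) || base_level < 1 || base_level > 100)
    stopf("`base_level` must lie in [1, 100]")
  if (!is_scalar_num(diurnal_amplitude) || diurnal_amplitude < 0)
    stopf("`diurnal_amplitude` must be >= 0")
  if (!is_scalar_num(diurnal_phase) || diurnal_phase < 0 || diurnal_phase >= 24)
    stopf("`diurnal_phase` must be a clock hour in [0, 24)")
  if (!is_scalar_num(ar_coefficient) || abs(ar_coefficient) >= 1)
    stopf("`ar_coefficient` must lie strictly inside (-1, 1)")
  if (!is_scalar_num(noise_sd) || noise_sd < 0)
    stopf("`noise_sd` must be >= 0")
  if (!is_scalar_num(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stopf("`missing_rate` must lie in [0, 1)")
  structure(list(cow_id = as.character(cow_id), base_level = base_level,
                 diurnal_amplitude = diurnal_amplitude,
                 diurnal_phase = diurnal_phase,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 missing_rate = missing_rate),
            class = "cow_profile")
}

#' Variance-inflation event
#'
#' Encodes the alternative hypothesis of the activity analysis: inside the
#' window `[t0 + start_offset, t0 + start_offset + duration)` the innovation
#' standard deviation of the AR(1) noise is multiplied by
#' `inflation_factor`. A factor of 1 is a no-op (the series is
#' distributionally unchanged).
#'
#' @param start_offset Signed offset of the event start from `t0`, in hours.
#' @param duration Event length in hours, > 0.
#' @param inflation_factor Multiplier on `noise_sd` inside the event, > 0.
#' @return List of class `variance_event`.
#' @export
variance_event <- function(start_offset, duration, inflation_factor) {
  if (!is_scalar_num(start_offset)) stopf("`start_offset` must be a number (hours)")
  if (!is_scalar_num(duration) || duration <= 0)
    stopf("`duration` must be a positive number of hours")
  if (!is_scalar_num(inflation_factor) || inflation_factor <= 0)
    stopf("`inflation_factor` must be > 0")
  structure(list(start_offset = start_offset, duration = duration,
                 inflation_factor = inflation_factor),
            class = "variance_event")
}

# Slot labels pre1..pre6, post1..post6 whose half-open interval intersects
# an event with inflation_factor != 1.
shifted_slot_labels <- function(events) {
  if (!length(events)) return(character())
  starts <- c(-24 + 4 * (0:5), 4 * (0:5))
  labels <- c(paste0("pre", 1:6), paste0("post", 1:6))
  hit <- vapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- starts[i] + 4
    any(vapply(events, function(ev) {
      ev$inflation_factor != 1 &&
        ev$start_offset < b && (ev$start_offset + ev$duration) > a
    }, logical(1)))
  }, logical(1))
  labels[hit]
}

#' Behavioral repertoire for the ethogram simulator
#'
#' The closed ethogram: five state behaviors (walking, standing, lying,
#' eating, drinking) that partition time, tail raising as a point event,
#' and tail rubbing / social interaction as interval behaviors observed in
#' parallel. `mean_dwell` (minutes) gives mean state dwell times and mean
#' interval lengths; `transition_weights` is the embedded-chain transition
#' weight matrix over the five states (self-transitions ignored).
#'
#' The default dwell times and transitions approximate the time budget
#' reported for peripartal cows in maternity pens (roughly 45% lying,
#' 34% standing, 15% eating, 3% walking, 2% drinking) while respecting
#' physical ordering (a lying cow stands up before doing anything else).
#'
#' @param mean_dwell Named numeric vector of mean dwell / interval lengths
#'   in minutes; must cover the five states, `rubbing_tail` and
#'   `social_interaction`, all > 0.
#' @param transition_weights 5x5 nonnegative matrix with dimnames equal to
#'   the state behaviors; row = current state, column = next state. The
#'   diagonal is ignored. A row whose off-diagonal weights are all zero is
#'   rejected (absorbing state).
#' @param tail_raise_rate Tail raises per hour (Poisson), >= 0.
#' @param rubbing_rate,social_rate Interval starts per hour (Poisson), >= 0.
#' @param subtype_weights Named nonnegative weights over the six social
#'   subtypes used when a social-interaction interval is emitted.
#' @return List of class `behavior_repertoire`.
#' @export
behavior_repertoire <- function(
    mean_dwell = c(walking = 4, standing = 35, lying = 75, eating = 30,
                   drinking = 3, rubbing_tail = 2, social_interaction = 2),
    transition_weights = NULL,
    tail_raise_rate = 1,
    rubbing_rate = 0.05,
    social_rate = 0.5,
    subtype_weights = c(social_licking = 0.30, sniffing_head = 0.30,
                        sniffing_body = 0.30, gentle_pushing = 0.05,
                        head_butting = 0.04, fighting = 0.01)) {
  states <- c("walking", "standing", "lying", "eating", "drinking")
  need <- c(states, "rubbing_tail", "social_interaction")
  if (!all(need %in% names(mean_dwell)))
    stopf("`mean_dwell` must name all of: %s", paste(need, collapse = ", "))
  if (any(mean_dwell[need] <= 0)) stopf("all `mean_dwell` entries must be > 0")
  if (is.null(transition_weights)) {
    transition_weights <- matrix(0, 5, 5, dimnames = list(states, states))
    transition_weights["lying", ]    <- c(0, 1, 0, 0, 0)
    transition_weights["standing", ] <- c(0.20, 0, 0.40, 0.30, 0.10)
    transition_weights["eating", ]   <- c(0.15, 0.55, 0.15, 0, 0.15)
    transition_weights["drinking", ] <- c(0.10, 0.60, 0.10, 0.20, 0)
    transition_weights["walking", ]  <- c(0, 0.45, 0.25, 0.25, 0.05)
  }
  tw <- as.matrix(transition_weights)
  if (!identical(dim(tw), c(5L, 5L)) ||
      !identical(rownames(tw), states) || !identical(colnames(tw), states))
    stopf("`transition_weights` must be a 5x5 matrix with the state behaviors as dimnames")
  if (any(tw < 0)) stopf("`transition_weights` must be nonnegative")
  diag(tw) <- 0
  if (any(rowSums(tw) == 0))
    stopf("absorbing state(s) in `transition_weights`: %s",
          paste(rownames(tw)[rowSums(tw) == 0], collapse = ", "))
  for (r in c(tail_raise_rate, rubbing_rate, social_rate))
    if (!is_scalar_num(r) || r < 0) stopf("event rates must be >= 0")
  subs <- c("social_licking", "sniffing_head", "sniffing_body",
            "gentle_pushing", "head_butting", "fighting")
  if (!all(subs %in% names(subtype_weights)) || any(subtype_weights[subs] < 0) ||
      sum(subtype_weights[subs]) <= 0)
    stopf("`subtype_weights` must be nonnegative weights over the six social subtypes")
  structure(list(state_behaviors = states,
                 point_behaviors = "tail_raising",
                 interval_behaviors = c("rubbing_tail", "social_interaction"),
                 social_subtypes = subs,
                 mean_dwell = mean_dwell[need],
                 transition_weights = tw,
                 tail_raise_rate = tail_raise_rate,
                 rubbing_rate = rubbing_rate,
                 social_rate = social_rate,
                 subtype_weights = subtype_weights[subs]),
            class = "behavior_repertoire")
}
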