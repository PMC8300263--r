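# Independent oracles used to cross-check the package's own implementations.
# These deliberately take the brute-force route.

# One-way ANOVA on |x - group median|: the textbook route to the
# Brown-Forsythe statistic, via lm/anova rather than the package formula.
bf_oracle <- function(a, b) {
  z <- c(abs(a - median(a)), abs(b - median(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  tab <- anova(lm(z ~ g))
  list(W = tab$`F value`[1L], p = tab$`Pr(>F)`[1L])
}

# Exhaustive sign-flip enumeration of the two-sided signed-rank p-value
# (feasible for n <= ~16). Zero differences dropped, mid-ranks for ties.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Deterministic event log: a repeating lying/standing cycle (exact tiling)
# with optional tail-raise points, identical on both video days so that
# pre/post slot outcomes match unless raises are injected.
make_cycle_log <- function(cow_id, t_start, span_hours,
                           cycle_min = c(lying = 30, standing = 30),
                           raises = NULL) {
  t_start <- as.POSIXct(t_start, tz = "UTC")
  period <- sum(cycle_min) * 60
  n_cyc <- ceiling(span_hours * 3600 / period)
  starts <- ends <- numeric(0); labs <- character(0)
  now <- as.numeric(t_start)
  stop_at <- as.numeric(t_start) + span_hours * 3600
  for (i in seq_len(n_cyc)) {
    for (b in names(cycle_min)) {
      if (now >= stop_at) break
      upto <- min(now + cycle_min[[b]] * 60, stop_at)
      starts <- c(starts, now); ends <- c(ends, upto); labs <- c(labs, b)
      now <- upto
    }
  }
  df <- data.frame(cow_id = cow_id, behavior = labs, subtype = NA_character_,
                   start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
                   end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"),
                   stringsAsFactors = FALSE)
  if (length(raises))
    df <- rbind(df, data.frame(
      cow_id = cow_id, behavior = "tail_raising", subtype = NA_character_,
      start = as.POSIXct(raises, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(NA), stringsAsFactors = FALSE))
  validate_event_log(df)
}

epoch_t0 <- function(hours = 120) as.POSIXct("2018-07-16", tz = "UTC") + hours * 3600
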