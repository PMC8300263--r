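t0 <- as.POSIXct("2018-08-01 10:00:00", tz = "UTC")

test_that("noise-free degenerate profile gives a constant series on the 10-min grid", {
  p <- cow_profile("c1", base_level = 40, diurnal_amplitude = 0,
                   ar_coefficient = 0, noise_sd = 0, missing_rate = 0)
  sim <- simulate_activity_series(p, t0, span_before = 24, span_after = 12, seed = 1)
  expect_equal(length(sim$series), 6 * 36)
  expect_true(all(sim$series$values == 40))
  expect_true(all(diff(as.numeric(sim$series$time)) == 600))
})

test_that("the generator is deterministic under its seed", {
  p <- cow_profile("c1")
  a <- simulate_activity_series(p, t0, 24, 12, seed = 7)
  b <- simulate_activity_series(p, t0, 24, 12, seed = 7)
  c <- simulate_activity_series(p, t0, 24, 12, seed = 8)
  expect_identical(a$series$values, b$series$values)
  expect_false(identical(a$series$values, c$series$values))
})

test_that("a variance event inflates the sample SD by its factor", {
  # memoryless noise so the SD ratio is exactly the inflation factor
  p <- cow_profile("c1", base_level = 50, diurnal_amplitude = 0,
                   ar_coefficient = 0, noise_sd = 3)
  hrs <- 10000 / 6
  sim <- simulate_activity_series(p, t0, span_before = hrs, span_after = hrs,
                                  events = list(variance_event(0, hrs, 3)),
                                  seed = 42)
  inside <- sim$series$values[sim$series$time >= t0]
  outside <- sim$series$values[sim$series$time < t0]
  expect_gt(length(inside), 9999)
  ratio <- sd(inside) / sd(outside)
  expect_lt(abs(ratio - 3) / 3, 0.05)
})

test_that("an inflation factor of 1 is a distributional no-op with empty truth", {
  p <- cow_profile("c1")
  plain <- simulate_activity_series(p, t0, 24, 24, seed = 5)
  noop <- simulate_activity_series(p, t0, 24, 24,
                                   events = list(variance_event(2, 6, 1)), seed = 5)
  expect_identical(plain$series$values, noop$series$values)
  expect_identical(noop$truth$shifted_slots, character(0))
})

test_that("truth labels exactly the slots intersecting an inflating event", {
  ev <- function(...) list(variance_event(...))
  sim <- function(events) simulate_activity_series(cow_profile(), t0, 120, 24,
                                                   events = events, seed = 1)$truth$shifted_slots
  expect_identical(sim(ev(4, 4, 3)), "post2")
  expect_identical(sim(ev(3, 2, 3)), c("post1", "post2"))
  expect_identical(sim(ev(-24, 48, 2)), c(paste0("pre", 1:6), paste0("post", 1:6)))
  expect_identical(sim(ev(-30, 2, 2)), character(0))  # before the slotted day
})

test_that("values are clamped to [1, 100] and missingness matches its rate", {
  p <- cow_profile("c1", base_level = 95, diurnal_amplitude = 20,
                   ar_coefficient = 0.5, noise_sd = 10, missing_rate = 0.3)
  sim <- simulate_activity_series(p, t0, 200, 200, seed = 3)
  expect_true(all(sim$series$values >= 1 & sim$series$values <= 100))
  n_grid <- 6 * 400
  dropped <- 1 - length(sim$series) / n_grid
  se <- sqrt(0.3 * 0.7 / n_grid)
  expect_lt(abs(dropped - 0.3), 3 * se)
})

test_that("invalid profiles and events are rejected with diagnostics", {
  expect_error(cow_profile(ar_coefficient = 1), "ar_coefficient")
  expect_error(cow_profile(missing_rate = 1), "missing_rate")
  expect_error(cow_profile(base_level = 0.5), "base_level")
  expect_error(variance_event(0, -4, 2), "duration")
  expect_error(variance_event(0, 4, 0), "inflation_factor")
  expect_error(simulate_activity_series(cow_profile(), t0, -24, 24, seed = 1),
               "positive")
  expect_error(simulate_activity_series(cow_profile(), t0, 24, 24), "seed")
})

test_that("a dominant-dwell repertoire yields a single lying record", {
  md <- c(walking = 4, standing = 35, lying = 1e9, eating = 30, drinking = 3,
          rubbing_tail = 2, social_interaction = 2)
  rep0 <- behavior_repertoire(mean_dwell = md, tail_raise_rate = 0,
                              rubbing_rate = 0, social_rate = 0)
  log <- simulate_ethogram(rep0, t0, span = 12, seed = 2)
  expect_identical(nrow(log), 1L)
  expect_identical(log$behavior, "lying")
  expect_equal(as.numeric(log$end - log$start, units = "hours"), 12)
  expect_identical(sum(log$behavior == "tail_raising"), 0L)
})

test_that("tail raises follow their Poisson rate", {
  rep2 <- behavior_repertoire(tail_raise_rate = 2)
  log <- simulate_ethogram(rep2, t0, span = 1000, seed = 9)
  n <- sum(log$behavior == "tail_raising")
  expect_lt(abs(n - 2000), 3 * sqrt(2000))
})

test_that("state behaviors tile the simulated span exactly", {
  for (seed in 1:5) {
    log <- simulate_ethogram(behavior_repertoire(), t0, span = 36, seed = seed)
    st <- log[log$behavior %in% c("walking", "standing", "lying", "eating", "drinking"), ]
    expect_equal(sum(as.numeric(st$end) - as.numeric(st$start)), 36 * 3600)
    expect_equal(min(as.numeric(st$start)), as.numeric(t0))
    # validate_event_log already enforced no gap/overlap
    expect_s3_class(log, "event_log")
  }
})

test_that("an absorbing transition row is rejected", {
  tw <- matrix(1, 5, 5,
               dimnames = list(c("walking", "standing", "lying", "eating", "drinking"),
                               c("walking", "standing", "lying", "eating", "drinking")))
  tw["lying", ] <- 0
  expect_error(behavior_repertoire(transition_weights = tw), "absorbing")
})

test_that("cohort simulation composes per-cow streams reproducibly", {
  coh <- simulate_cohort(18, seed = 11)
  expect_length(coh, 18)
  expect_true(all(vapply(coh, function(x) length(x$truth$shifted_slots) == 0, logical(1))))
  # distinct attachment clock times on the 10-minute grid
  tod <- vapply(coh, function(x) as.numeric(x$t0) %% 86400, numeric(1))
  expect_identical(anyDuplicated(tod), 0L)
  expect_true(all(tod %% 600 == 0))
  # cohort member 1 equals a direct call with the split seed and same t0
  direct <- simulate_activity_series(cow_profile("cow1"), coh[[1]]$t0,
                                     seed = tailsense:::split_seed(11, 1))
  expect_identical(coh[[1]]$series$values, direct$series$values)
})

test_that("video cows get 36-hour logs spanning both observation windows", {
  coh <- simulate_cohort(9, seed = 13, n_video = 9)
  expect_true(all(!vapply(coh, function(x) is.null(x$log), logical(1))))
  for (x in coh[1:3]) {
    st <- x$log[x$log$behavior %in% c("walking", "standing", "lying", "eating", "drinking"), ]
    expect_equal(min(st$start), x$t0 - 24 * 3600)
    expect_equal(max(st$end), x$t0 + 12 * 3600)
  }
})

test_that("truth sidecars round-trip through JSON", {
  sim <- simulate_activity_series(cow_profile("c9"), t0,
                                  events = list(variance_event(4, 4, 3)), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, path)
  back <- jsonlite::read_json(path)
  expect_identical(back[[1]]$cow_id, "c9")
  expect_identical(unlist(back[[1]]$shifted_slots), "post2")
  expect_equal(back[[1]]$events[[1]]$inflation_factor, 3)
})
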