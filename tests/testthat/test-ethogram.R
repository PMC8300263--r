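t0 <- epoch_t0()
H <- 3600
states <- c("walking", "standing", "lying", "eating", "drinking")

rec <- function(behavior, from_min, to_min = NA, subtype = NA_character_,
                cow_id = "c1") {
  data.frame(cow_id = cow_id, behavior = behavior, subtype = subtype,
             start = t0 + from_min * 60,
             end = if (is.na(to_min)) as.POSIXct(NA) else t0 + to_min * 60,
             stringsAsFactors = FALSE)
}

test_that("the ethogram is closed and primary states must tile the span", {
  expect_s3_class(validate_event_log(rec("lying", 0, 240)), "event_log")
  expect_error(validate_event_log(rbind(rec("standing", 0, 120),
                                        rec("standing", 60, 180))), "overlap")
  expect_error(validate_event_log(rbind(rec("lying", 0, 60),
                                        rec("standing", 90, 120))), "gap")
  expect_error(validate_event_log(rec("grazing", 0, 60)), "unknown behavior")
  expect_error(validate_event_log(rec("tail_raising", 0, 10)), "no end")
  expect_error(validate_event_log(rec("social_interaction", 0, 5)), "subtype")
  ok <- validate_event_log(rbind(rec("lying", 0, 240),
                                 rec("social_interaction", 10, 12, "sniffing_head"),
                                 rec("tail_raising", 30)))
  expect_identical(nrow(ok), 3L)
})

test_that("slot summaries clip, accumulate and normalise correctly", {
  slot <- c(t0, t0 + 4 * H)
  all_lying <- validate_event_log(rec("lying", 0, 240))
  s <- slot_summary(all_lying, slot)
  expect_equal(s$duration_minutes[["lying"]], 240)
  expect_equal(unname(s$proportions["lying"]), 1)
  expect_equal(sum(s$proportions), 1)
  # record straddling the slot edge contributes only its inside part
  log2 <- validate_event_log(rbind(rec("lying", -60, 30), rec("standing", 30, 300)))
  s2 <- slot_summary(log2, slot)
  expect_equal(s2$duration_minutes[["lying"]], 30)
  expect_equal(s2$duration_minutes[["standing"]], 210)
  # hand-built budget: lying 120, standing 60, eating 40, walking 15, drinking 5
  log3 <- validate_event_log(rbind(rec("lying", 0, 120), rec("standing", 120, 180),
                                   rec("eating", 180, 220), rec("walking", 220, 235),
                                   rec("drinking", 235, 240)))
  s3 <- slot_summary(log3, slot)
  expect_equal(unname(s3$proportions[c("lying", "standing", "eating",
                                       "walking", "drinking")]),
               c(120, 60, 40, 15, 5) / 240)
  expect_error(slot_summary(log3, c(t0 + 5 * H, t0 + 9 * H)), "outside the coded span")
})

test_that("bout counting merges eating/drinking into standing but not walking", {
  slot <- c(t0, t0 + 4 * H)
  log <- validate_event_log(rbind(rec("lying", 0, 60), rec("standing", 60, 90),
                                  rec("eating", 90, 120), rec("lying", 120, 240)))
  expect_identical(count_bouts(log, slot),
                   c(standing_bouts = 1L, lying_bouts = 2L))
  expect_identical(count_bouts(validate_event_log(rec("lying", 0, 240)), slot),
                   c(standing_bouts = 0L, lying_bouts = 1L))
  # alternating lying/standing every 30 min starting with lying
  alt <- validate_event_log(do.call(rbind, lapply(0:7, function(i)
    rec(if (i %% 2 == 0) "lying" else "standing", i * 30, (i + 1) * 30))))
  expect_identical(count_bouts(alt, slot),
                   c(standing_bouts = 4L, lying_bouts = 4L))
  # walking terminates both bout types
  walk <- validate_event_log(rbind(rec("lying", 0, 60), rec("walking", 60, 70),
                                   rec("lying", 70, 240)))
  expect_identical(count_bouts(walk, slot),
                   c(standing_bouts = 0L, lying_bouts = 2L))
})

test_that("durations and bouts are invariant to splitting a record", {
  slot <- c(t0, t0 + 4 * H)
  set.seed(55)
  for (i in 1:25) {
    log <- simulate_ethogram(behavior_repertoire(), t0, 4, seed = 500 + i)
    st_rows <- which(log$behavior %in% states)
    j <- sample(st_rows, 1)
    mid <- log$start[j] + as.numeric(log$end[j] - log$start[j]) / 2
    split <- rbind(log[seq_len(j - 1), ],
                   within(log[j, ], end <- mid),
                   within(log[j, ], start <- mid),
                   log[-seq_len(j), ])
    split <- validate_event_log(split)
    expect_identical(count_bouts(split, slot), count_bouts(log, slot))
    expect_equal(slot_summary(split, slot)$duration_minutes,
                 slot_summary(log, slot)$duration_minutes)
  }
})

test_that("slot totals are additive over a partition of the slot", {
  log <- simulate_ethogram(behavior_repertoire(), t0, 4, seed = 66)
  whole <- slot_summary(log, c(t0, t0 + 4 * H))$duration_minutes
  parts <- lapply(0:3, function(i)
    slot_summary(log, c(t0 + i * H, t0 + (i + 1) * H))$duration_minutes)
  expect_equal(Reduce(`+`, parts), whole)
})

test_that("the paired Wilcoxon handles degenerate and hand-checked cases", {
  same <- wilcoxon_signed_rank(c(3, 1, 4), c(3, 1, 4))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  r <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))
  expect_false(r$degenerate)
  expect_identical(r$n_nonzero, 3L)
  p_exact <- exact_signed_rank_p(c(1, 2, 3))
  expect_equal(p_exact, 0.25)
  expect_identical(r$p_value < 0.05, p_exact < 0.05)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
  expect_error(wilcoxon_signed_rank(1, 2), "at least 2")
})

test_that("the approximation tracks the exact oracle for cohort-sized samples", {
  set.seed(99)
  for (i in 1:40) {
    pre <- rnorm(9); post <- pre + rnorm(9, 0.4)
    pa <- wilcoxon_signed_rank(pre, post)$p_value
    pe <- exact_signed_rank_p(post - pre)
    expect_lt(abs(pa - pe), 0.02)
  }
})

cycle_cohort <- function(n = 4, raise_plan = NULL) {
  # logs covering t0-24h .. t0+12h; identical behavior on both days
  logs <- lapply(seq_len(n), function(i)
    make_cycle_log(paste0("c", i), t0 - 24 * H, 36,
                   raises = if (is.null(raise_plan)) NULL else raise_plan[[i]]))
  names(logs) <- paste0("c", seq_len(n))
  schemes <- lapply(seq_len(n), function(i) build_window_scheme(t0))
  names(schemes) <- names(logs)
  list(logs = logs, schemes = schemes)
}

test_that("identical pre/post behavior gives three degenerate comparisons", {
  co <- cycle_cohort(4)
  res <- compare_slot_pairs(co$logs, co$schemes, "lying")
  expect_identical(nrow(res), 3L)
  expect_identical(res$slot_index, 1:3)
  expect_true(all(res$degenerate))
  expect_true(all(res$p_value == 1))
})

test_that("a single outlier cow can carry a slot comparison", {
  # post-pre tail-raise differences -1, 2, -3, 4, ..., 8 plus one huge cow
  diffs <- c(-1, 2, -3, 4, 5, 6, 7, 8, 100)
  plan <- lapply(diffs, function(d) {
    pre_n <- 10; post_n <- 10 + d
    c(as.numeric(t0 - 24 * H) + seq_len(pre_n) * 60,       # video pre slot 1
      as.numeric(t0) + seq_len(post_n) * 60)               # video post slot 1
  })
  co <- cycle_cohort(9, raise_plan = plan)
  res <- compare_slot_pairs(co$logs, co$schemes, "tail_raising")
  expect_lt(res$p_value[1], 0.05)
  dropped <- sensitivity_drop_cow(co$logs, co$schemes, "tail_raising", "c9")
  expect_gt(dropped$p_value[1], 0.05)
  expect_identical(dropped$n_pairs[1], 8L)
  expect_error(sensitivity_drop_cow(co$logs, co$schemes, "tail_raising", "c99"),
               "unknown cow_id")
})

test_that("cows missing a video window are excluded with a warning", {
  co <- cycle_cohort(3)
  co$logs[["c3"]] <- make_cycle_log("c3", t0 - 6 * H, 18)  # starts too late
  expect_warning(res <- compare_slot_pairs(co$logs, co$schemes, "standing"),
                 "excluding 1 cow")
  expect_identical(res$n_pairs[1], 2L)
})

test_that("a doubled post-attachment tail-raise rate is detected at n = 9", {
  # power check at the study's video cohort size
  reps <- behavior_repertoire(tail_raise_rate = 1)
  detections <- vapply(1:20, function(k) {
    logs <- lapply(1:9, function(i) {
      pre_part <- simulate_ethogram(reps, t0 - 24 * H, 24,
                                    seed = 9000 + 100 * k + i,
                                    cow_id = paste0("c", i))
      post_part <- simulate_ethogram(behavior_repertoire(tail_raise_rate = 4),
                                     t0, 12, seed = 9050 + 100 * k + i,
                                     cow_id = paste0("c", i))
      validate_event_log(rbind(as.data.frame(pre_part), as.data.frame(post_part)))
    })
    names(logs) <- paste0("c", 1:9)
    schemes <- lapply(1:9, function(i) build_window_scheme(t0))
    names(schemes) <- names(logs)
    res <- compare_slot_pairs(logs, schemes, "tail_raising")
    any(res$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(detections), 0.75)
})
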