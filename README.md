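# tailsense

Does attaching a calving sensor to a dairy cow's tail disturb the animal?
`tailsense` implements a two-pronged statistical screen for that question,
built for precision-livestock researchers working with rumen-bolus
activity data and coded video observation around a sensor-attachment time
`t0`:

1. **Activity variability.** The bolus reports a dimensionless activity
   index (1–100) every 10 minutes. After removing a 10–15 min attachment
   buffer and detrending by first differences, the spread of each 4-hour
   slot in the 24 h after attachment is compared with a four-day baseline
   (`t0 − 96 h .. t0`) by the Brown–Forsythe test — Levene's
   variance-homogeneity test with group medians,

   W = (N−k)/(k−1) · Σⱼ nⱼ(z̄ⱼ − z̄)² / ΣⱼΣᵢ(zᵢⱼ − z̄ⱼ)²,  zᵢⱼ = |xᵢⱼ − medianⱼ|,

   with k = 2 and Bonferroni control over the six slots of a period
   (corrected threshold 0.05/6 ≈ 0.0083). The same machinery is applied
   to the previous day against its own baseline (`t0 − 120 .. t0 − 24 h`)
   as a within-animal control, and the headline statistic is the change
   in the number of slots showing a significant *increase* in
   variability, post versus pre.

2. **Ethogram observation.** Coded behavior logs (walking / standing /
   lying / eating / drinking states that partition time, tail-raise point
   events, tail-rubbing and social-interaction intervals) are summarised
   per 4-hour video slot — durations, tail-raise counts, standing/lying
   bouts with eating and drinking merged into standing — and matching
   pre/post slots are compared with paired, continuity-corrected Wilcoxon
   signed-rank tests, including a leave-one-cow-out sensitivity re-test.

Because data of this kind are rarely shareable, the package ships a
first-class synthetic-data module (diurnal sinusoid + AR(1) activity with
optional variance-inflation events and ground truth; semi-Markov ethogram
logs) so the whole pipeline can be exercised, calibrated and
power-checked without any download. See the vignette
(`vignettes/activity-variability.Rmd`) for the full methods account.

## Worked example

Simulate one cow whose noise variability triples for the first four hours
after attachment, then run the per-cow analysis:

```r
library(tailsense)

t0  <- as.POSIXct("2018-08-06 09:30:00", tz = "UTC")
sim <- simulate_activity_series(cow_profile("cow7"), t0,
                                events = list(variance_event(0, 4, 3)),
                                seed = 11)
tab <- analyze_cow(sim$series, t0)
tab[, c("label", "mad_baseline", "mad_slot", "W", "p_value",
        "direction", "significant_corrected")]
#>    label mad_baseline mad_slot        W  p_value direction significant_corrected
#> 1   pre1         3.51     3.42  0.02603 8.72e-01  decrease                 FALSE
#> ...
#> 7  post1         3.50     8.35 65.68028 3.00e-15  increase                  TRUE
#> ...
#> 12 post6         3.50     3.97  0.73823 3.91e-01  increase                 FALSE

count_significant(tab)
#> significant slots (bonferroni): pre 0 increase / 0 decrease; post 1 increase / 0 decrease
compare_pre_post(count_significant(tab))
#> [1] 1
attr(tab, "adf")$post
#> ADF (constant, 5 lag(s), n = 136): tau = -6.214, p <= 0.01 -> stationary
```

Only the slot actually covered by the injected event (`post1`,
`t0 .. t0 + 4 h`) is flagged: its detrended mean absolute deviation
around the median (8.35) far exceeds the baseline's (3.50), the
Brown–Forsythe p-value clears the corrected threshold, and the
post-minus-pre increase count of +1 is the disturbance signature the
procedure looks for. All eleven other slots behave like baseline.

`run_pipeline()` drives everything (per-cow tables, the cohort-average
analysis, significant-slot counts, and the ethogram comparisons when
behavior logs are present) from one config, for either simulated cohorts
or delimited-text exports of real data; `run_calibration()` measures
type-I calibration and power of the whole procedure by simulation.

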