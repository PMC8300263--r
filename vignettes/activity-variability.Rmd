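---
title: "Detecting disturbance after calving-sensor attachment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting disturbance after calving-sensor attachment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailsense)
```

## The question

Tail-attached calving sensors promise earlier calving detection, but the
device itself may disturb the cow it is meant to protect. `tailsense`
implements a two-pronged screen for such disturbance around the attachment
time `t0`:

1. **Activity variability.** A reticulorumen bolus reports a dimensionless
   activity index (1–100) every 10 minutes. If the sensor agitates the cow,
   the *variability* of this index — not necessarily its level — should
   increase after attachment. The package tests each 4-hour slot of the
   24 hours after `t0` against a four-day baseline, and, as a within-animal
   control, each slot of the previous day against its own four-day
   baseline.
2. **Ethogram observation.** For a video-recorded subgroup, coded behavior
   (walking, standing, lying, eating, drinking; tail raising; tail rubbing;
   social interaction) is summarised per 4-hour slot and compared between
   matching pre/post slots with paired Wilcoxon signed-rank tests.

Both approaches use the cow as her own control: pre and post slots at the
same clock time of day are compared against baselines at the same diurnal
phase, so ordinary daily rhythm does not masquerade as disturbance.

## Approach 1: the variance-change procedure

### Windows

All intervals are half-open `[start, end)` at 1-second timestamp
resolution:

| window | interval | role |
|---|---|---|
| post baseline | `[t0 − 96 h, t0)` | reference for the post-sensor day |
| pre baseline | `[t0 − 120 h, t0 − 24 h)` | reference for the control day |
| post slots 1–6 | tile `[t0, t0 + 24 h)` | tested day |
| pre slots 1–6 | tile `[t0 − 24 h, t0)` | within-animal control day |

A four-day baseline is long enough to be representative of usual activity
while excluding management events (drying off, moving to the maternity
pen) further in the past. The slot pairs `pre_i`/`post_i` sit exactly 24 h
apart, i.e. at the same time of day.

### Buffer, detrending, stationarity

The physical act of attachment contaminates the reading(s) closest to
`t0`, so every point in `[t0, t0 + 10 min)` is dropped. On the device's
10-minute grid this yields an effective buffer of 10–15 minutes whatever
the phase of `t0`, and the rule is idempotent.

Slow trends and the diurnal level cycle are removed by consecutive first
differences, computed separately for the pre-segment
(`[t0 − 120 h, t0)`) and the post-segment (`[t0, t0 + 24 h)`) so that no
difference ever spans the intervention itself. Differences are suppressed
across recording gaps wider than 1.5× the cadence, and each difference is
stamped at the later point of its pair (so a difference "belongs" to the
slot in which it is observed). Stationarity of the differenced series is
confirmed by an augmented Dickey–Fuller test with constant, no trend, and
lag order `floor((n − 1)^(1/3))` — the standard default when nothing is
known about the short-run dynamics. The tau quantile table for the
constant-only case is built in and interpolated in both dimensions; the
pass decision at level 0.01 is taken against the interpolated critical
value, so clipping of printed p-values at the table edge cannot flip it.

### The test

For baseline values `x` and slot values `y` (both on the detrended scale)
the Brown–Forsythe statistic is Levene's test with medians:
`z = |value − group median|`, and

$$W \;=\; \frac{N-k}{k-1}\cdot
  \frac{\sum_j n_j(\bar z_j - \bar z)^2}{\sum_j\sum_i (z_{ij}-\bar z_j)^2},
  \qquad k = 2,$$

referred to `F(k−1, N−k)`. The median-based transform is robust to the
clearly non-normal activity index, and the test tolerates the unequal
group sizes (≈576-point baseline vs ≈24-point slot) inherent to the
window scheme. The group mean of `z` is exactly the **mean absolute
deviation around the median** (MAD in the package's output — *not* the
median absolute deviation), which is also the dispersion summary reported
per window; a slot is labelled an *increase* when its detrended MAD
exceeds its baseline's, with exact ties labelled *decrease* — the
conservative choice for a statistic that counts increases. Medians of
even-sized sets use the midpoint convention throughout.

Within each period the six slot tests form one Bonferroni family:
the corrected threshold is `0.05/6 ≈ 0.0083`. The headline statistic is
the count of significant-*increase* slots post-sensor minus the same
count pre-sensor (`compare_pre_post()`); a disturbance signature is a
positive difference, not a large absolute count, because cows routinely
show episodes of high or low variability on any day.

Slots with detrended coverage below 0.5 are flagged untested rather than
tested on a sliver of data; untested slots can never be significant.

### Per-cow and cohort-average analyses

`analyze_cow()` runs the full pipeline for one animal.
`analyze_cohort()` first aligns all cows on the offset from their own
`t0` (attachment happens at a different clock time for each animal),
snaps offsets to the 10-minute grid, averages across cows present at each
offset (dropping offsets with fewer than half the cows), and then runs the
identical per-cow pipeline on the averaged series. Averaging precedes
detrending, so what is tested is the variability of the cohort-mean
index. The alternative — detrending first and averaging the differences —
commutes for gap-free data but not in the presence of missingness; the
averaging-first order is the one that matches "testing the average
activity index".

## Approach 2: the ethogram procedure

The closed ethogram has five state behaviors that partition time
(`validate_event_log()` enforces exact tiling), tail raising as a point
event (defined observationally as lateral elevation beyond 90°; the
geometry is metadata, not computed), and tail rubbing and social
interaction as parallel intervals, each social interval carrying exactly
one of six subtypes.

Video slots are three 4-hour slots tiling `[t0, t0 + 12 h)` and, as
control, three tiling `[t0 − 24 h, t0 − 12 h)` — the same clock hours the
day before. Per slot, `slot_summary()` clips records to the slot and
accumulates durations (minutes), counts tail raises, and computes bout
counts. Two conventions matter:

* **Bout mapping.** Eating and drinking happen while standing and are
  merged into *standing* for bout counting. Walking is deliberately
  *not* merged: the rule that defines the merge names only eating and
  drinking, so walking remains its own state and terminates both standing
  and lying bouts. A lying–walking–lying sequence is two lying bouts.
* **Edge bouts.** A bout already in progress at slot start is counted in
  the slot. This makes counts invariant to splitting a record into two
  adjacent records of the same state — a property the test suite checks —
  and avoids any dependence on how the coder happened to segment a bout.

Pre/post pairs (slot `i` vs slot `i`) are compared per behavior with the
paired Wilcoxon signed-rank test in its continuity-corrected
normal-approximation form (zero differences dropped, mid-ranks for ties).
The continuity correction only exists in the approximate variant, which
is therefore the implementation; exhaustive sign-flip enumeration is kept
as an independent oracle in the test suite. At the video cohort size of
nine animals the worst-case absolute error of the approximation over all
possible statistic values is 0.019, and no value of the statistic can
make the approximate and exact tests disagree at the 0.05 level, so the
approximation is fully adequate at this design size. Bout outcomes are
emitted separately for standing and lying (both are reported; neither is
privileged as "the" bout outcome). `sensitivity_drop_cow()` repeats any
comparison with one animal excluded — the standard probe when a single
cow appears to carry a significant result.

## The synthetic-data module

Field data of this kind are rarely shareable (restricted video, farm
privacy), so the package carries a generator that reproduces the
statistical structure the analysis relies on, with ground truth:

* **Activity** (`simulate_activity_series()`): clamped diurnal sinusoid
  plus AR(1) noise on the 10-minute grid. Defaults: base level 30,
  diurnal amplitude 10 peaking at 14:00, AR coefficient 0.7, innovation
  SD 4, no missingness. The strong persistence is deliberate and
  realistic: behavioral bouts last much longer than one 10-minute sample,
  so adjacent index values are highly correlated. It is also what makes
  the downstream test calibrated — first differences of a *weakly*
  autocorrelated series carry lag-1 autocorrelation near −0.5, which a
  variance test on slot means feels as miscalibration, whereas the
  differences of a strongly persistent series are nearly exchangeable,
  matching the procedure's premise that differencing yields a
  well-behaved stationary series. Variance events multiply the innovation
  SD inside a chosen window; `sim_truth` records exactly which slots any
  inflating event touches.
* **Behavior** (`simulate_ethogram()`): a semi-Markov chain over the five
  states (exponential dwells, embedded transition weights with
  physically sensible structure — a lying cow stands up before anything
  else), Poisson tail raises, Poisson-started exponential-length rubbing
  and social intervals. The default dwell means and transitions
  approximate the reported peripartal time budget (~45% lying,
  ~34% standing, ~15% eating, ~3% walking, ~2% drinking).
* **Cohorts** (`simulate_cohort()`): per-cow seeds split deterministically
  from one cohort seed; attachment times drawn at distinct clock times on
  the 10-minute grid, mirroring the real heterogeneity that motivates the
  same-clock-time window pairing.

What the generator does **not** emulate: the proprietary index's actual
marginal distribution (unknown beyond range and cadence — generator
parameters are design choices, *not* estimates of the real device),
calving-related behavioral drift, health events, or any coupling between
the activity stream and the behavioral log of the same cow. Passing the
calibration suite therefore demonstrates the statistical machinery is
correct under the stated model, not that the model is the true data
process.

## Calibration and power

`run_calibration()` measures the operating characteristics of the entire
per-cow procedure (buffer → detrend → slice → test → correct):

```{r, eval = FALSE}
cal <- run_calibration(list(seed = 1), n_replicates = 2000)
pow <- run_calibration(list(seed = 2,
                            events = list(variance_event(4, 4, 3))),
                       n_replicates = 500)
```

The package's chosen study sizes are 2000 replicates for null calibration
(per-slot binomial SE ≈ 0.005 around 0.05) and 500 for power against the
reference alternative — a 3× innovation-SD inflation covering exactly one
post slot. The test suite asserts that every per-slot raw rejection rate
lies in [0.03, 0.07], that the corrected per-period family-wise rate stays
at or below 0.07, and that the reference alternative is recovered at the
corrected level in at least 90% of replicates. `scripts/acceptance.R`
recomputes all of these from scratch at any seed.

## Numerical and degenerate-case conventions

* Half-open intervals everywhere; 1-second timestamps; 10-minute nominal
  cadence.
* Brown–Forsythe with both groups constant is an error (degenerate); one
  constant group is fine (the denominator comes from the varying group);
  perfectly separated absolute deviations give `W = Inf`, `p = 0`.
* An all-zero difference vector in the Wilcoxon gives a flagged
  degenerate result with `p = 1` rather than an error, since "nothing
  changed" is a meaningful outcome of a pre/post comparison.
* ADF on a constant series is an error; p-values are clipped to the
  tabulated range [0.01, 0.99].
* The ethogram simulator rounds segment boundaries (not durations) to the
  1-second grid, so state records keep tiling the span exactly.
* All simulators take explicit seeds and restore the caller's RNG state.

## Limitations

* The activity generator is a stand-in, clearly labelled synthetic; no
  claim is made that its parameters describe any commercial device.
* The cohort-average analysis assumes missingness is unrelated to the
  attachment response; offsets missing for more than half the cows are
  simply dropped.
* The ADF specification (constant, no trend, cube-root lag rule) is one
  standard choice among several; the specification used is recorded in
  every result object for auditability.
* Behavioral comparisons at n = 9 have limited power; the package reports
  medians and MADs alongside p-values so that effect direction and size
  remain visible.
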