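Package: tailsense
Title: Disturbance Screening for Tail-Attached Calving Sensors from
    Activity Variability and Ethogram Observation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate whether attaching a calving sensor to a dairy
    cow's tail disturbs the animal. Implements windowed variance-homogeneity
    change detection on rumen-bolus activity-index time series (dual four-day
    baselines, six four-hour slots before and after attachment,
    first-difference detrending with an augmented Dickey-Fuller stationarity
    check, Brown-Forsythe tests with Bonferroni control, and
    significant-slot counting) together with ethogram-based behavioral slot
    summaries compared pre/post attachment by paired Wilcoxon signed-rank
    tests. A synthetic-data module generates activity series and behavioral
    event logs with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
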