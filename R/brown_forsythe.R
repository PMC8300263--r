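#' Mean absolute deviation around the median
#'
#' The robust spread measure reported alongside every variance test here:
#' the *mean* of `|x - median(x)|` (not the median absolute deviation).
#' The median of an even-sized set is the midpoint of the two central
#' order statistics.
#'
#' @param values Nonempty numeric vector.
#' @return A single number >= 0.
#' @examples
#' mad_around_median(c(1, 2, 4, 7))  # 2
#' @export
mad_around_median <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    stopf("`values` must be nonempty with no missing entries")
  mean(abs(values - median(values)))
}

#' Brown--Forsythe test of variance homogeneity (two groups)
#'
#' Levene's test with group medians in the absolute-deviation transform:
#' with `z_ij = |x_ij - median_j|`, the statistic is
#' \deqn{W = \frac{N-k}{k-1} \cdot
#'   \frac{\sum_j n_j (\bar z_j - \bar z)^2}{\sum_j \sum_i (z_ij - \bar z_j)^2}}
#' with `k = 2` groups here, referred to the F distribution with
#' `(k - 1, N - k)` degrees of freedom. The median-based transform makes
#' the test robust to non-normal activity data, and it tolerates the
#' heavily unequal group sizes of a 4-day baseline against a 4-hour slot.
#'
#' The direction label is `"increase"` when the slot's mean absolute
#' deviation around its median exceeds the baseline's, else `"decrease"`
#' (ties count as decrease, conservative for the increase-counting
#' statistic). If the between-group deviations are nonzero while every
#' within-group deviation vanishes, `W = Inf` and `p = 0`; if both groups
#' are constant the input is degenerate and rejected.
#'
#' @param baseline Numeric values of the baseline window (>= 3).
#' @param slot Numeric values of the tested slot (>= 3).
#' @return List of class `brown_forsythe`: `W`, `df_between`, `df_within`,
#'   `p_value`, `group_sizes` (baseline, slot), `mad` (baseline, slot),
#'   `direction`.
#' @export
brown_forsythe <- function(baseline, slot) {
  baseline <- as.numeric(baseline); slot <- as.numeric(slot)
  if (length(baseline) < 3L || length(slot) < 3L)
    stopf("each group needs at least 3 values (have %d and %d)",
          length(baseline), length(slot))
  if (anyNA(baseline) || anyNA(slot)) stopf("missing values in input")
  za <- abs(baseline - median(baseline))
  zb <- abs(slot - median(slot))
  ma <- mean(za); mb <- mean(zb)
  na <- length(za); nb <- length(zb); N <- na + nb; k <- 2L
  zbar <- (na * ma + nb * mb) / N
  num <- na * (ma - zbar)^2 + nb * (mb - zbar)^2
  den <- sum((za - ma)^2) + sum((zb - mb)^2)
  if (den == 0 && num == 0)
    stopf("degenerate input: no spread in the absolute deviations of either group")
  W <- if (den == 0) Inf else (N - k) / (k - 1L) * num / den
  p <- if (is.infinite(W)) 0 else 1 - pf(W, k - 1L, N - k)
  structure(list(W = W, df_between = k - 1L, df_within = N - k,
                 p_value = p, group_sizes = c(baseline = na, slot = nb),
                 mad = c(baseline = ma, slot = mb),
                 direction = if (mb > ma) "increase" else "decrease"),
            class = "brown_forsythe")
}

#' @export
print.brown_forsythe <- function(x, ...) {
  cat(sprintf("Brown-Forsythe: W(%d, %d) = %.4g, p = %.4g, direction: %s\n",
              x$df_between, x$df_within, x$W, x$p_value, x$direction))
  cat(sprintf("MAD baseline = %.4g (n = %d), MAD slot = %.4g (n = %d)\n",
              x$mad[1L], x$group_sizes[1L], x$mad[2L], x$group_sizes[2L]))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#'
#' Divides the family-wise significance level by the number of tests in the
#' family. For the six 4-hour slots of one period at family level 0.05 the
#' corrected threshold is 0.05/6 = 0.00833..., conventionally displayed as
#' 0.0083.
#'
#' @param family_level Family-wise level in (0, 1).
#' @param m Number of tests in the family, >= 1.
#' @return The per-test threshold `family_level / m` at full precision.
#' @export
bonferroni_threshold <- function(family_level, m) {
  if (!is_scalar_num(family_level) || family_level <= 0 || family_level >= 1)
    stopf("`family_level` must lie strictly between 0 and 1")
  if (!is_scalar_num(m) || m < 1 || m != round(m))
    stopf("`m` must be a positive integer number of tests")
  family_level / m
}
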