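# Evaluation battery over (predicted GA, reference GA) pairs: banded MAE,
# paired Wilcoxon signed-rank comparison of absolute errors, Bland-Altman
# agreement, time-to-prediction distribution, and shuffle-consistency.

#' Mean absolute error by gestational-age band
#'
#' Bands are half-open `[lo, hi)` intervals in weeks of *reference* GA. The
#' default breakpoints give the bands 10-14, 14-18, 18-24, 24-30 and 30-36
#' weeks.
#'
#' @param records data.frame with `predicted_ga_days` and
#'   `reference_ga_days`.
#' @param breaks_weeks increasing numeric vector of band edges, weeks.
#' @return data.frame with `band`, `n`, `mae_days` (`NA` for empty bands).
#' @export
mae_by_band <- function(records, breaks_weeks = c(10, 14, 18, 24, 30, 36)) {
  stopifnot(nrow(records) > 0, !is.unsorted(breaks_weeks, strictly = TRUE))
  err <- abs(records$predicted_ga_days - records$reference_ga_days)
  wk <- records$reference_ga_days / 7
  k <- length(breaks_weeks) - 1
  out <- data.frame(
    band = sprintf("%g-%g", breaks_weeks[-(k + 1)], breaks_weeks[-1]),
    n = 0L, mae_days = NA_real_)
  for (i in seq_len(k)) {
    in_band <- wk >= breaks_weeks[i] & wk < breaks_weeks[i + 1]
    out$n[i] <- sum(in_band)
    if (out$n[i] > 0) out$mae_days[i] <- mean(err[in_band])
  }
  out
}

#' Paired Wilcoxon signed-rank comparison of absolute errors
#'
#' Two-sided signed-rank test on the paired differences of absolute errors
#' (model vs comparator). Zero differences are dropped (Wilcoxon's original
#' rule). The exact null distribution is used for n <= 25 when the absolute
#' differences are tie-free; otherwise the normal approximation with
#' continuity correction.
#'
#' @param abs_err_model,abs_err_comparator equal-length numeric vectors of
#'   absolute errors in days.
#' @return List `p_value`, `n_effective` (pairs after dropping zeros),
#'   `statistic` (V, sum of positive ranks), `degenerate` (`TRUE` with
#'   `p_value = 1` when every difference is zero), `method`.
#' @export
paired_wilcoxon <- function(abs_err_model, abs_err_comparator) {
  stopifnot(length(abs_err_model) == length(abs_err_comparator))
  d <- abs_err_model - abs_err_comparator
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p_value = 1, n_effective = 0L, statistic = NA_real_,
                degenerate = TRUE, method = "degenerate (all differences zero)"))
  }
  use_exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(p_value = unname(wt$p.value), n_effective = n,
       statistic = unname(wt$statistic), degenerate = FALSE,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Bland-Altman agreement analysis
#'
#' Differences are `predicted - reference`; limits of agreement are
#' `mean(diff) +/- 1.96 * sd(diff)`.
#'
#' @param records data.frame with `predicted_ga_days` and
#'   `reference_ga_days`.
#' @return List `mean_diff_days`, `sd_diff_days`, `loa` (lower, upper; `NA`
#'   when n < 3), and `points` — a plot-ready data.frame of pair means and
#'   differences.
#' @export
bland_altman <- function(records) {
  stopifnot(nrow(records) > 0)
  diffs <- records$predicted_ga_days - records$reference_ga_days
  means <- (records$predicted_ga_days + records$reference_ga_days) / 2
  m <- mean(diffs)
  s <- if (length(diffs) >= 3) stats::sd(diffs) else NA_real_
  list(mean_diff_days = m, sd_diff_days = s,
       loa = if (is.na(s)) c(NA_real_, NA_real_) else m + c(-1.96, 1.96) * s,
       points = data.frame(mean_days = means, diff_days = diffs))
}

#' Empirical distribution of time-to-prediction
#'
#' `NA` times are right-censored at the video end: they count in the
#' denominator but are never treated as reached at any time, so the CDF can
#' plateau below 1.
#'
#' @param times_s numeric vector of seconds; `NA` = confidence never
#'   reached.
#' @return List `cdf` (a function of t), `median_s` (smallest t with
#'   CDF >= 0.5; `NA` if the CDF never reaches 0.5), `n`, `n_censored`.
#' @export
time_to_prediction_cdf <- function(times_s) {
  stopifnot(length(times_s) > 0)
  n <- length(times_s)
  reached <- sort(times_s[!is.na(times_s)])
  cdf <- function(t) vapply(t, function(ti) sum(reached <= ti) / n, numeric(1))
  median_s <- if (length(reached) >= ceiling(n / 2)) {
    reached[ceiling(n / 2)]
  } else NA_real_
  list(cdf = cdf, median_s = median_s, n = n,
       n_censored = sum(is.na(times_s)))
}

#' Shuffle-consistency of paired video estimates
#'
#' For pairs of estimates from independently re-shuffled clips of the same
#' scan, reports the fraction of pairs whose GA estimates differ by strictly
#' less than `threshold_days`.
#'
#' @param ga_a,ga_b equal-length vectors of GA estimates (days) from the two
#'   shuffles.
#' @param threshold_days agreement threshold (default 3 days; strict `<`).
#' @return Fraction in \[0, 1\].
#' @export
shuffle_consistency <- function(ga_a, ga_b, threshold_days = 3) {
  stopifnot(length(ga_a) == length(ga_b), length(ga_a) > 0)
  mean(abs(ga_a - ga_b) < threshold_days)
}
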