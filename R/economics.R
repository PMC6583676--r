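#' Trimmed-mean price range for a list of daily prices
#'
#' Summarizes a wide international price list into low/median/high daily
#' prices: with `m` the overall mean, the "high" value is the mean of the
#' prices that are not more than 50% below `m` (`p >= 0.5 m`), the "low"
#' value is the mean of the prices not more than 50% above `m`
#' (`p <= 1.5 m`), and the median is the sample median of the untrimmed
#' list. The median is reported alongside the trimmed means because the two
#' notions need not coincide; a warning flags a range where the median falls
#' outside \[low, high\].
#'
#' @param prices Non-empty numeric vector of non-negative prices (EUR/day).
#' @return List of class `price_range` with elements `low`, `median`, `high`
#'   and attribute `mean` (the untrimmed mean).
#' @export
price_range <- function(prices) {
  if (length(prices) == 0L) stop("price list must be non-empty")
  if (any(!is.finite(prices)) || any(prices < 0))
    stop("prices must be finite and non-negative")
  m <- mean(prices)
  out <- list(low = mean(prices[prices <= 1.5 * m]),
              median = stats::median(prices),
              high = mean(prices[prices >= 0.5 * m]))
  if (out$median < out$low || out$median > out$high)
    warning("median price falls outside the trimmed-mean [low, high] range")
  structure(out, mean = m, class = "price_range")
}

#' Treatment cost at a horizon
#'
#' Daily price times months times days per month. The placebo price is 0 by
#' convention, so its cost is 0 at every horizon. `days_per_month` defaults
#' to 30; a 59-day preset reproduces published pCGS cost tables that imply a
#' 177-day quarter (see the methods vignette).
#'
#' @param price_per_day Price in EUR/day (>= 0).
#' @param t_months Horizon in months (>= 0).
#' @param days_per_month Days charged per month (default 30).
#' @return Cost in EUR.
#' @export
cost_at <- function(price_per_day, t_months, days_per_month = 30) {
  if (any(price_per_day < 0) || any(t_months < 0) || any(days_per_month < 0))
    stop("price, horizon and days_per_month must be non-negative")
  price_per_day * t_months * days_per_month
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Computes incremental cost and incremental QALYs of the active arm versus
#' the comparator and classifies the comparison: a ratio (EUR/QALY) is
#' reported only when both increments have the same strict sign; the
#' comparator dominates when the intervention is no more effective yet at
#' least as costly (`incremental_qaly <= 0` and `incremental_cost >= 0`, not
#' both zero) -- the published tables print this as "Placebo better"; the
#' intervention dominates in the mirror case. Two exactly-zero increments
#' give an indeterminate verdict with a warning.
#'
#' @param cost_active,cost_placebo Costs in EUR.
#' @param qaly_active,qaly_placebo Effects in QALYs.
#' @param horizon_months Optional label carried into the result.
#' @return List of class `icer_result` with `incremental_cost`,
#'   `incremental_qaly`, `verdict` (`"ratio"`, `"comparator_dominates"`,
#'   `"intervention_dominates"` or `"indeterminate"`) and `icer` (EUR/QALY,
#'   `NA` unless the verdict is `"ratio"`).
#' @export
icer <- function(cost_active, cost_placebo, qaly_active, qaly_placebo,
                 horizon_months = NA) {
  stopifnot(is.finite(cost_active), is.finite(cost_placebo),
            is.finite(qaly_active), is.finite(qaly_placebo))
  dc <- cost_active - cost_placebo
  dq <- qaly_active - qaly_placebo
  if (dc == 0 && dq == 0) {
    warning("both increments are exactly zero: indeterminate comparison")
    verdict <- "indeterminate"
    ratio <- NA_real_
  } else if (dq <= 0 && dc >= 0) {
    verdict <- "comparator_dominates"
    ratio <- NA_real_
  } else if (dq >= 0 && dc <= 0) {
    verdict <- "intervention_dominates"
    ratio <- NA_real_
  } else {
    verdict <- "ratio"
    ratio <- dc / dq
  }
  structure(list(horizon_months = horizon_months, incremental_cost = dc,
                 incremental_qaly = dq, verdict = verdict, icer = ratio),
            class = "icer_result")
}

#' Classify an ICER against a willingness-to-pay threshold
#'
#' @param icer_result An [icer()] result.
#' @param wtp_threshold Willingness-to-pay threshold in EUR/QALY (> 0;
#'   default 30000).
#' @return One of `"cost_effective"`, `"not_cost_effective"`, `"dominated"`,
#'   `"dominant"`, `"indeterminate"`.
#' @export
classify_icer <- function(icer_result, wtp_threshold = 30000) {
  stopifnot(inherits(icer_result, "icer_result"), wtp_threshold > 0)
  switch(icer_result$verdict,
         comparator_dominates = "dominated",
         intervention_dominates = "dominant",
         indeterminate = "indeterminate",
         ratio = if (icer_result$icer <= wtp_threshold) "cost_effective"
                 else "not_cost_effective")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("ICER comparison",
      if (!is.na(x$horizon_months)) paste0(" at ", x$horizon_months, " months"),
      ":\n", sep = "")
  cat(sprintf("  incremental cost: %.4f EUR\n  incremental QALY: %.8f\n",
              x$incremental_cost, x$incremental_qaly))
  if (x$verdict == "ratio") {
    cat(sprintf("  ICER: %.1f EUR/QALY\n", x$icer))
  } else {
    cat("  verdict:", x$verdict, "\n")
  }
  invisible(x)
}
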