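#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost, QALYs and life-years, ICERs per QALY and per
#' LY, incremental net monetary benefit at the willingness-to-pay threshold,
#' and the dominance status. The ICER is reported only in the trade-off
#' quadrants; when one arm is cheaper and more effective the comparison is
#' `"dominant"`/`"dominated"` and the ratio is `NA`.
#'
#' @param intervention,comparator `arm_result` objects on the same economic
#'   parameters.
#' @param wtp Willingness-to-pay per unit of effect, USD.
#' @param effect `"qaly"` or `"ly"`: effect measure used for `icer`, `inmb`
#'   and dominance.
#' @return A `comparison` object: `d_cost`, `d_qaly`, `d_ly`, `icer`,
#'   `icer_qaly`, `icer_ly`, `inmb`, `dominance`, `wtp`, `effect`.
#' @export
compare_arms <- function(intervention, comparator, wtp, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"), wtp >= 0)
  d_cost <- intervention$totals$cost_total - comparator$totals$cost_total
  d_qaly <- intervention$totals$qaly - comparator$totals$qaly
  d_ly <- intervention$totals$ly - comparator$totals$ly
  d_eff <- if (effect == "qaly") d_qaly else d_ly
  ratio <- function(dc, de) {
    if (de == 0) return(NA_real_)
    if ((dc > 0 && de > 0) || (dc < 0 && de < 0)) dc / de else NA_real_
  }
  dominance <- if (d_eff == 0) {
    "boundary"
  } else if (d_cost <= 0 && d_eff > 0) {
    "dominant"
  } else if (d_cost >= 0 && d_eff < 0) {
    "dominated"
  } else {
    "trade-off"
  }
  structure(list(
    intervention = intervention$arm, comparator = comparator$arm,
    d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
    icer = ratio(d_cost, d_eff),
    icer_qaly = ratio(d_cost, d_qaly), icer_ly = ratio(d_cost, d_ly),
    inmb = wtp * d_eff - d_cost,
    dominance = dominance, wtp = wtp, effect = effect),
    class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s (%s):\n", x$intervention, x$comparator,
              x$effect))
  cat(sprintf("  dCost %.0f, dQALY %.3f, dLY %.3f\n", x$d_cost, x$d_qaly,
              x$d_ly))
  cat(sprintf("  ICER %s, INMB %.0f at WTP %.0f [%s]\n",
              if (is.na(x$icer)) x$dominance else sprintf("%.0f", x$icer),
              x$inmb, x$wtp, x$dominance))
  invisible(x)
}

#' Incremental net monetary benefit at a given threshold
#' @param comparison A [compare_arms()] result.
#' @param wtp Willingness-to-pay, USD per unit of the comparison's effect.
#' @return INMB = WTP x incremental effect - incremental cost, USD.
#' @export
inmb <- function(comparison, wtp) {
  stopifnot(inherits(comparison, "comparison"), wtp >= 0)
  d_eff <- if (comparison$effect == "qaly") comparison$d_qaly
           else comparison$d_ly
  wtp * d_eff - comparison$d_cost
}

#' Cumulative incremental net-benefit series per cycle
#' @inheritParams compare_arms
#' @return Data frame: `time` (months), cumulative `d_cost`, `d_effect`,
#'   `inmb`.
#' @export
inmb_series <- function(intervention, comparator, wtp,
                        effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  ci <- intervention$cycles
  cc <- comparator$cycles
  stopifnot(nrow(ci) == nrow(cc), all(abs(ci$time - cc$time) < 1e-9))
  eff_col <- if (effect == "qaly") "qaly" else "ly"
  d_cost <- cumsum(ci$cost - cc$cost)
  d_eff <- cumsum(ci[[eff_col]] - cc[[eff_col]])
  data.frame(time = ci$time, d_cost = d_cost, d_effect = d_eff,
             inmb = wtp * d_eff - d_cost)
}

#' Break-even year of the cumulative incremental net benefit
#'
#' Finds the first time at which the cumulative discounted INMB becomes
#' non-negative and stays non-negative through the horizon, linearly
#' interpolated within the crossing cycle.
#'
#' @inheritParams compare_arms
#' @return Break-even time in years, or `NA` if the cumulative INMB never
#'   settles non-negative.
#' @export
breakeven_year <- function(intervention, comparator, wtp,
                           effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  ser <- inmb_series(intervention, comparator, wtp, effect)
  v <- ser$inmb
  n <- length(v)
  suffix_min <- rev(cummin(rev(v)))
  ok <- which(v >= 0 & suffix_min >= 0)
  if (length(ok) == 0L) return(NA_real_)
  j <- ok[1L]
  if (j == 1L) return(ser$time[1L] / 12)  # within the first cycle
  t0 <- ser$time[j - 1L]; t1 <- ser$time[j]
  v0 <- v[j - 1L]; v1 <- v[j]
  t_cross <- if (v1 == v0) t1 else t0 + (t1 - t0) * (0 - v0) / (v1 - v0)
  t_cross / 12
}

#' One-call comparison from a configuration
#' @param config Full configuration.
#' @param intervention,comparator Arm names.
#' @param effect Effect measure.
#' @return A `comparison`.
#' @export
compare_config <- function(config, intervention, comparator,
                           effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  compare_arms(run_arm(config, intervention), run_arm(config, comparator),
               wtp = config$econ$wtp, effect = effect)
}
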