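#' State occupancy of a three-state partitioned survival model
#'
#' Allocates the cohort among progression-free (PF), progressed disease (PD)
#' and death directly from the PFS and OS curves:
#' PF(t) = min(PFS(t), OS(t)), PD(t) = max(0, OS(t) - PFS(t)),
#' dead(t) = 1 - OS(t). Where a fitted PFS curve crosses above OS at large
#' times, PF is clipped to OS, so occupancies are never negative and always
#' sum to one.
#'
#' @param pfs,os Curves accepted by [surv_prob()].
#' @param grid Cycle times in months, starting at 0, uniformly spaced.
#' @return Data frame (`time`, `pf`, `pd`, `dead`) of class `state_trace`.
#' @export
state_occupancy <- function(pfs, os, grid) {
  stopifnot(length(grid) >= 2, grid[1] == 0)
  dg <- diff(grid)
  if (max(abs(dg - dg[1])) > 1e-9) {
    stop("grid must be uniformly spaced", call. = FALSE)
  }
  s_pfs <- surv_prob(pfs, grid)
  s_os <- surv_prob(os, grid)
  out <- data.frame(time = grid,
                    pf = pmin(s_pfs, s_os),
                    pd = pmax(0, s_os - s_pfs),
                    dead = 1 - s_os)
  class(out) <- c("state_trace", "data.frame")
  out
}

# expected aggregate per-AE disutility of an arm under a granularity policy
ae_decrement_rate <- function(arm, econ, granularity) {
  if (identical(granularity, "event-specific")) {
    if (is.null(arm$ae_events)) stop("arm has no event-specific AE table",
                                     call. = FALSE)
    sum(arm$ae_events$prob * arm$ae_events$disutility)
  } else {
    arm$p_ae * econ$du_ae
  }
}

#' Accumulate discounted costs, life-years and QALYs for one arm
#'
#' Integrates state occupancy over cycles by the trapezoid rule. Time in PF
#' accrues annual medication plus (conversion-factor adjusted) non-medication
#' costs and PF utility minus the administration-route disutility; time in PD
#' accrues (conversion-factor adjusted) supportive-care cost and PD utility.
#' Discounting uses `(1 + r)^(-t)` at cycle midpoints. The adverse-event
#' disutility is applied according to the AE timing policy: `"first-cycle"`
#' (default) decrements PF time during the treatment-initiation window (the
#' first month, one default cycle, independent of the grid resolution),
#' `"first-6-months"` every cycle with PF occupancy during the first six
#' months, `"every-cycle"` all cycles. A one-time testing cost may be
#' charged at t = 0.
#'
#' @param trace A [state_occupancy()] result.
#' @param arm One arm's block of the configuration (see [base_config()]).
#' @param econ The `econ` block of the configuration.
#' @param ae_policy,ae_granularity AE timing and aggregation policies.
#' @return An `arm_result`: the trace, per-cycle discounted cost/QALY/LY
#'   vectors, and discounted totals (cost components, LY, QALY, overall and
#'   in PF).
#' @export
accumulate <- function(trace, arm, econ,
                       ae_policy = c("first-cycle", "first-6-months",
                                     "every-cycle"),
                       ae_granularity = c("aggregate", "event-specific")) {
  ae_policy <- match.arg(ae_policy)
  ae_granularity <- match.arg(ae_granularity)
  stopifnot(inherits(trace, "state_trace"))
  stopifnot(econ$u_pf >= 0, econ$u_pf <= 1, econ$u_pd >= 0, econ$u_pd <= 1,
            econ$discount >= 0, econ$conv_factor > 0, econ$conv_factor <= 1)
  n <- nrow(trace) - 1L
  t0 <- trace$time[-(n + 1L)]
  t1 <- trace$time[-1L]
  dt <- t1 - t0
  # person-time (years) per cycle via trapezoid of occupancy
  pf_t <- (trace$pf[-(n + 1L)] + trace$pf[-1L]) / 2 * dt / 12
  pd_t <- (trace$pd[-(n + 1L)] + trace$pd[-1L]) / 2 * dt / 12
  df <- (1 + econ$discount)^(-((t0 + t1) / 2) / 12)

  route_du <- if (identical(arm$route, "iv")) econ$du_iv else 0
  cost_med <- pf_t * arm$cost_med_annual * df
  cost_nonmed <- pf_t * arm$cost_nonmed_annual * econ$conv_factor * df
  cost_pd <- pd_t * arm$cost_supportive_annual * econ$conv_factor * df
  cost <- cost_med + cost_nonmed + cost_pd
  if (isTRUE(econ$include_testing)) cost[1L] <- cost[1L] + econ$testing_cost

  qaly_pf <- pf_t * (econ$u_pf - route_du) * df
  qaly_pd <- pd_t * econ$u_pd * df
  dec_rate <- ae_decrement_rate(arm, econ, ae_granularity)
  ae_window <- econ$ae_window_months %||% 1
  ae_dec <- switch(ae_policy,
    "first-cycle" = ifelse(t1 <= ae_window + 1e-9, dec_rate * pf_t * df, 0),
    "first-6-months" = ifelse(t1 <= 6 + 1e-9, dec_rate * pf_t * df, 0),
    "every-cycle" = dec_rate * pf_t * df
  )
  qaly <- qaly_pf + qaly_pd - ae_dec
  ly <- (pf_t + pd_t) * df
  ly_pf <- pf_t * df

  structure(list(
    trace = trace,
    cycles = data.frame(time = t1, cost = cost, qaly = qaly, ly = ly),
    totals = list(
      cost_med = sum(cost_med), cost_nonmed = sum(cost_nonmed),
      cost_pf = sum(cost_med) + sum(cost_nonmed) +
        if (isTRUE(econ$include_testing)) econ$testing_cost else 0,
      cost_pd = sum(cost_pd), cost_total = sum(cost),
      ly = sum(ly), ly_pf = sum(ly_pf),
      qaly = sum(qaly), qaly_pf = sum(qaly_pf - ae_dec)),
    arm = arm$label %||% "arm"),
    class = "arm_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.arm_result <- function(x, ...) {
  with(x$totals, cat(sprintf(
    "<arm_result> %s: cost %.0f (PF %.0f, PD %.0f), LY %.2f, QALY %.2f\n",
    x$arm, cost_total, cost_pf, cost_pd, ly, qaly)))
  invisible(x)
}

#' Run one arm of the partitioned survival model
#'
#' Builds the arm's PFS/OS curves (parametric or hybrid), computes state
#' occupancy on the cycle grid implied by the configuration's horizon and
#' cycle length, and accumulates discounted outcomes.
#'
#' @param config Full configuration (see [base_config()]).
#' @param arm_name Name of the arm inside `config$arms`.
#' @return An `arm_result`.
#' @examples
#' run_arm(base_config(), "pemigatinib")
#' @export
run_arm <- function(config, arm_name) {
  arm <- config$arms[[arm_name]]
  if (is.null(arm)) stop("unknown arm: ", arm_name, call. = FALSE)
  econ <- config$econ
  grid <- seq(0, econ$horizon_years * 12, by = econ$cycle_months)
  trace <- state_occupancy(build_curve(arm$pfs), build_curve(arm$os), grid)
  accumulate(trace, arm, econ,
             ae_policy = config$ae_policy %||% "first-cycle",
             ae_granularity = config$ae_granularity %||% "aggregate")
}

#' Run every arm of the model
#' @param config Full configuration.
#' @param arms Arm names (default: all).
#' @return Named list of `arm_result` objects.
#' @export
run_model <- function(config, arms = names(config$arms)) {
  stats::setNames(lapply(arms, function(a) run_arm(config, a)), arms)
}

#' Table-2-shaped summary of a model run
#' @param results Named list of `arm_result`s from [run_model()].
#' @return Data frame with one row per quantity and one column per arm.
#' @export
summarize_arms <- function(results) {
  keys <- c("cost_total", "cost_pf", "cost_med", "cost_nonmed", "cost_pd",
            "ly_pf", "ly", "qaly_pf", "qaly")
  out <- data.frame(quantity = keys)
  for (nm in names(results)) {
    out[[nm]] <- vapply(keys, function(k) results[[nm]]$totals[[k]],
                        numeric(1))
  }
  out
}
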