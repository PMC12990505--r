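# shared fixtures: small, built in code at test time

base_cfg <- psmcea::base_config()

# tiny hand-checkable data sets
ipd_four_events <- pseudo_ipd(time = 1:4, event = rep(1L, 4))
ipd_mixed <- pseudo_ipd(time = 1:4, event = c(1L, 0L, 1L, 0L))
ipd_all_censored <- pseudo_ipd(time = 1:4, event = rep(0L, 4))

# a fake arm_result carrying only per-cycle series (for break-even tests)
fake_arm <- function(time_months, cost, qaly, ly = qaly, label = "fake") {
  structure(list(cycles = data.frame(time = time_months, cost = cost,
                                     qaly = qaly, ly = ly),
                 totals = list(cost_total = sum(cost), qaly = sum(qaly),
                               ly = sum(ly)),
                 arm = label),
            class = "arm_result")
}

# a fake psa_result with explicit per-iteration outcomes
fake_psa <- function(cost, qaly) {
  structure(list(cost = cost, qaly = qaly, ly = qaly,
                 n_iter = nrow(cost), seed = 0L, arms = colnames(cost),
                 n_redraws = 0L),
            class = "psa_result")
}

# independent daily-step accumulator: rectangle rule on a fine grid with
# per-step discounting; deliberately shares no code with accumulate()
daily_oracle <- function(config, arm_name, step_days = 1) {
  arm <- config$arms[[arm_name]]
  econ <- config$econ
  dt <- step_days / 30
  grid <- seq(0, econ$horizon_years * 12, by = dt)
  pfs <- psmcea:::build_curve(arm$pfs)
  os <- psmcea:::build_curve(arm$os)
  s_pfs <- surv_prob(pfs, grid)
  s_os <- surv_prob(os, grid)
  pf <- pmin(s_pfs, s_os)
  pd <- pmax(0, s_os - s_pfs)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  pf_m <- (pf[-1] + pf[-length(pf)]) / 2
  pd_m <- (pd[-1] + pd[-length(pd)]) / 2
  df <- (1 + econ$discount)^(-mid / 12)
  route_du <- if (identical(arm$route, "iv")) econ$du_iv else 0
  pf_t <- pf_m * dt / 12
  pd_t <- pd_m * dt / 12
  cost <- sum(pf_t * (arm$cost_med_annual +
                        arm$cost_nonmed_annual * econ$conv_factor) * df) +
    sum(pd_t * arm$cost_supportive_annual * econ$conv_factor * df)
  # first-cycle AE policy: decrement over the first month of PF time
  first <- mid <= config$econ$cycle_months
  ae <- arm$p_ae * econ$du_ae * sum(pf_t[first] * df[first])
  list(cost = cost,
       ly = sum((pf_t + pd_t) * df),
       qaly = sum(pf_t * (econ$u_pf - route_du) * df) +
         sum(pd_t * econ$u_pd * df) - ae)
}
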