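test_that("state occupancy partitions the cohort", {
  grid <- seq(0, 480, by = 1)
  pfs <- parametric_survival("log-normal", c(meanlog = 1.988, sdlog = 0.989))
  os <- parametric_survival("log-logistic", c(scale = 18.387, shape = 1.626))
  tr <- state_occupancy(pfs, os, grid)
  expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-12))
  expect_true(all(tr$pf >= 0 & tr$pd >= 0 & tr$dead >= 0))
  expect_equal(unlist(tr[1, c("pf", "pd", "dead")], use.names = FALSE),
               c(1, 0, 0))

  # identical curves leave nobody in the progressed state
  tr2 <- state_occupancy(os, os, grid)
  expect_true(all(tr2$pd == 0))
})

test_that("a crossing PFS fit is clipped to OS, never negative occupancy", {
  # heavy-tailed PFS exceeds a thin-tailed OS at large times
  pfs <- parametric_survival("log-logistic", c(scale = 10, shape = 1.1))
  os <- parametric_survival("weibull", c(shape = 1.6, scale = 14))
  grid <- seq(0, 480, by = 1)
  expect_gt(surv_prob(pfs, 400), surv_prob(os, 400))  # they do cross
  tr <- state_occupancy(pfs, os, grid)
  expect_true(all(tr$pf <= surv_prob(os, grid) + 1e-15))
  expect_true(all(tr$pd >= 0))
  expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-12))
})

test_that("undiscounted unit-utility survival accrues time one-for-one", {
  # S identically 1 over 10 years (an all-censored KM): LY = QALY = 10
  km_flat <- km_curve(pseudo_ipd(rep(121, 5), rep(0L, 5)))
  grid <- seq(0, 120, by = 1)
  tr <- state_occupancy(km_flat, km_flat, grid)
  arm <- list(label = "flat", route = "oral", cost_med_annual = 0,
              cost_nonmed_annual = 0, cost_supportive_annual = 0, p_ae = 0)
  econ <- list(u_pf = 1, u_pd = 1, du_ae = 0, du_iv = 0, discount = 0,
               conv_factor = 1, include_testing = FALSE)
  res <- accumulate(tr, arm, econ)
  expect_equal(res$totals$ly, 10, tolerance = 1e-12)
  expect_equal(res$totals$qaly, 10, tolerance = 1e-12)
  expect_equal(res$totals$cost_total, 0)
})

test_that("exponential state times match closed forms at monthly cycles", {
  # PFS rate 1/20, OS rate 1/40 per month: expected PF time = 20 months,
  # expected PD time = 40 - 20 = 20 months
  pfs <- parametric_survival("exponential", c(rate = 1 / 20))
  os <- parametric_survival("exponential", c(rate = 1 / 40))
  grid <- seq(0, 2000, by = 1)
  tr <- state_occupancy(pfs, os, grid)
  arm <- list(label = "x", route = "oral", cost_med_annual = 12,
              cost_nonmed_annual = 0, cost_supportive_annual = 12, p_ae = 0)
  econ <- list(u_pf = 1, u_pd = 1, du_ae = 0, du_iv = 0, discount = 0,
               conv_factor = 1, include_testing = FALSE)
  res <- accumulate(tr, arm, econ)
  expect_equal(res$totals$ly_pf, 20 / 12, tolerance = 1e-3)
  expect_equal(res$totals$ly, 40 / 12, tolerance = 1e-3)
  # cost rates of 12/year convert state time to months of cost
  expect_equal(res$totals$cost_med, 20, tolerance = 1e-2)
  expect_equal(res$totals$cost_pd, 20, tolerance = 1e-2)
})

test_that("QALYs never exceed life-years and respect monotone inputs", {
  res <- run_arm(base_cfg, "pemigatinib")
  expect_lt(res$totals$qaly, res$totals$ly)
  expect_lt(res$totals$qaly_pf, res$totals$ly_pf)

  # raising a cost rate weakly raises total cost
  up <- set_config_path(base_cfg, "arms.pemigatinib.cost_nonmed_annual", 20000)
  expect_gt(run_arm(up, "pemigatinib")$totals$cost_total,
            res$totals$cost_total)
  # raising PF utility weakly raises QALYs
  up2 <- set_config_path(base_cfg, "econ.u_pf", 0.9)
  expect_gt(run_arm(up2, "pemigatinib")$totals$qaly, res$totals$qaly)
})

test_that("zero discount reproduces undiscounted sums exactly", {
  cfg0 <- set_config_path(base_cfg, "econ.discount", 0)
  res <- run_arm(cfg0, "mfolfox")
  tr <- res$trace
  dt <- diff(tr$time)
  ly_direct <- sum((tr$pf[-1] + tr$pf[-nrow(tr)]) / 2 * dt +
                     (tr$pd[-1] + tr$pd[-nrow(tr)]) / 2 * dt) / 12
  expect_equal(res$totals$ly, ly_direct, tolerance = 1e-12)
})

test_that("halving the cycle length moves every total by less than 0.5%", {
  fine <- set_config_path(base_cfg, "econ.cycle_months", 0.5)
  for (arm in names(base_cfg$arms)) {
    a <- run_arm(base_cfg, arm)$totals
    b <- run_arm(fine, arm)$totals
    for (k in c("cost_total", "cost_pf", "cost_pd", "ly", "qaly")) {
      expect_lt(abs(a[[k]] - b[[k]]) / abs(b[[k]]), 0.005)
    }
  }
})

test_that("a daily-step brute-force accumulator agrees with the engine", {
  for (arm in names(base_cfg$arms)) {
    engine <- run_arm(base_cfg, arm)$totals
    oracle <- daily_oracle(base_cfg, arm)
    expect_equal(engine$cost_total, oracle$cost, tolerance = 0.005)
    expect_equal(engine$ly, oracle$ly, tolerance = 0.005)
    expect_equal(engine$qaly, oracle$qaly, tolerance = 0.005)
  }
})

test_that("AE timing policies order QALYs as expected", {
  res_first <- run_arm(base_cfg, "pemigatinib")$totals$qaly
  cfg6 <- base_cfg; cfg6$ae_policy <- "first-6-months"
  cfg_all <- base_cfg; cfg_all$ae_policy <- "every-cycle"
  res6 <- run_arm(cfg6, "pemigatinib")$totals$qaly
  res_all <- run_arm(cfg_all, "pemigatinib")$totals$qaly
  expect_gt(res_first, res6)
  expect_gt(res6, res_all)

  # event-specific AE aggregation changes only via the expected decrement
  cfg_ev <- base_cfg; cfg_ev$ae_granularity <- "event-specific"
  res_ev <- run_arm(cfg_ev, "pemigatinib")$totals$qaly
  ev <- base_cfg$arms$pemigatinib$ae_events
  expect_lt(sum(ev$prob * ev$disutility),
            base_cfg$arms$pemigatinib$p_ae * base_cfg$econ$du_ae)
  expect_gt(res_ev, res_first)
})

test_that("the one-time testing fee enters at t = 0 when enabled", {
  cfg_t <- set_config_path(base_cfg, "econ.include_testing", TRUE)
  with_fee <- run_arm(cfg_t, "pemigatinib")$totals
  without <- run_arm(base_cfg, "pemigatinib")$totals
  expect_equal(with_fee$cost_total - without$cost_total,
               base_cfg$econ$testing_cost, tolerance = 1e-9)
})

test_that("hybrid curves hand off continuously and consistently", {
  tail <- parametric_survival("log-logistic", c(scale = 18.387, shape = 1.626))
  # switch time zero: identical to the pure parametric curve
  hy0 <- hybrid_curve(NULL, tail, 0)
  tt <- c(0, 3, 17, 60, 240)
  expect_equal(surv_prob(hy0, tt), surv_prob(tail, tt))

  spec <- sim_spec("log-logistic", c(scale = 18.387, shape = 1.626),
                   n = 10000, cutoff_months = 50, seed = 55)
  km <- km_curve(simulate_ipd(spec))
  hy <- hybrid_curve(km, tail, 36)
  # KM below the switch, rescaled tail above, non-increasing throughout
  grid <- seq(0, 480, by = 0.5)
  s <- surv_prob(hy, grid)
  expect_true(all(diff(s) <= 1e-12))
  expect_equal(surv_prob(hy, 20), surv_prob(km, 20))
  # continuity at the handoff
  expect_equal(surv_prob(hy, 36 + 1e-9), surv_prob(km, 36), tolerance = 1e-6)
  # self-consistency: KM from the same family stays near the pure curve
  expect_lt(max(abs(s - surv_prob(tail, grid))), 0.03)

  expect_error(hybrid_curve(km, tail, 100), "within the KM follow-up")
  dead_tail <- parametric_survival("weibull", c(shape = 5, scale = 1))
  expect_error(hybrid_curve(km, dead_tail, 36), "zero at the switch")
})
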