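test_that("PSA distribution means reproduce their base values", {
  # gamma(shape, rate) mean = shape/rate; the chemotherapy medication cost
  draws <- withr::with_seed(3, vapply(1:100000, function(i) {
    psmcea:::draw_psa_dist(dist_gamma(41.39, 0.003115), NA)$value
  }, numeric(1)))
  expect_equal(mean(draws), 41.39 / 0.003115, tolerance = 0.01)  # ~13,287

  # the default space's gamma/beta means sit near their base values
  space <- default_param_space(base_cfg)
  for (p in space) {
    m <- switch(p$dist$type,
                gamma = p$dist$shape / p$dist$rate,
                beta = p$dist$a / (p$dist$a + p$dist$b),
                uniform = (p$dist$lo + p$dist$hi) / 2,
                NA_real_)
    if (!is.na(m)) expect_equal(m, p$base, tolerance = 0.06)
  }
})

test_that("a degenerate DSA range produces zero swing", {
  space <- list(psa_param("fixed param", "econ.u_pd", 0.68, 0.68, 0.68))
  tor <- run_dsa(base_cfg, space)
  expect_equal(tor$swing, 0)
  expect_equal(tor$icer_low, tor$icer_high)
})

test_that("tornado ordering equals a brute-force sort of recomputed swings", {
  space <- default_param_space(base_cfg)[c(1, 2, 13, 19, 20, 27)]
  tor <- run_dsa(base_cfg, space)
  brute <- vapply(space, function(p) {
    icer_at <- function(v) {
      compare_config(psmcea:::apply_param(base_cfg, p, v),
                     "pemigatinib", "mfolfox")$icer
    }
    abs(icer_at(p$high) - icer_at(p$low))
  }, numeric(1))
  expect_equal(tor$swing, sort(brute, decreasing = TRUE), tolerance = 1e-9)
})

test_that("the published upper bound on drug cost breaks cost-effectiveness", {
  cfg_hi <- set_config_path(base_cfg, "arms.pemigatinib.cost_med_annual",
                            122057)
  cmp <- compare_config(cfg_hi, "pemigatinib", "mfolfox")
  expect_gt(cmp$icer, base_cfg$econ$wtp)
})

test_that("threshold search matches an affine oracle and handles no-crossing", {
  # INMB is exactly affine in the annual drug cost, so two model runs give
  # the root in closed form
  path <- "arms.pemigatinib.cost_med_annual"
  inmb_at <- function(v) {
    compare_config(set_config_path(base_cfg, path, v),
                   "pemigatinib", "mfolfox")$inmb
  }
  f0 <- inmb_at(73235); f1 <- inmb_at(122057)
  analytic <- 73235 - f0 * (122057 - 73235) / (f1 - f0)
  found <- threshold_search(base_cfg, path, c(73235, 122057))
  expect_equal(found, analytic, tolerance = 1e-5)

  # no sign change on the bracket: no threshold
  expect_true(is.na(threshold_search(base_cfg, path, c(73235, 80000))))
})

test_that("PSA with all-fixed distributions reproduces the base case", {
  space <- lapply(default_param_space(base_cfg), function(p) {
    p$dist <- dist_fixed(); p
  })
  psa <- run_psa(base_cfg, space, n_iter = 3, seed = 1,
                 arms = c("pemigatinib", "mfolfox"))
  det <- run_model(base_cfg)
  for (a in c("pemigatinib", "mfolfox")) {
    expect_equal(unname(psa$cost[, a]),
                 rep(det[[a]]$totals$cost_total, 3), tolerance = 1e-12)
    expect_equal(unname(psa$qaly[, a]),
                 rep(det[[a]]$totals$qaly, 3), tolerance = 1e-12)
  }
  # degenerate PSA carries no decision uncertainty
  expect_equal(evpi(psa, base_cfg$econ$wtp), 0)
})

test_that("PSA results are bit-identical under the same seed", {
  psa1 <- run_psa(base_cfg, n_iter = 20, seed = 123,
                  arms = c("pemigatinib", "mfolfox"))
  psa2 <- run_psa(base_cfg, n_iter = 20, seed = 123,
                  arms = c("pemigatinib", "mfolfox"))
  expect_identical(psa1$cost, psa2$cost)
  expect_identical(psa1$qaly, psa2$qaly)
})

test_that("CEAC values equal a brute-force recount and pair-sum to one", {
  psa <- run_psa(base_cfg, n_iter = 200, seed = 7,
                 arms = c("pemigatinib", "mfolfox"))
  grid <- c(0, 50000, 97048, 200000)
  curve <- ceac(psa, "pemigatinib", "mfolfox", grid)
  for (i in seq_along(grid)) {
    d_q <- psa$qaly[, "pemigatinib"] - psa$qaly[, "mfolfox"]
    d_c <- psa$cost[, "pemigatinib"] - psa$cost[, "mfolfox"]
    expect_equal(curve$probability[i], mean(grid[i] * d_q - d_c >= 0))
  }
  # at WTP 0 the curve is the probability of being cheaper
  expect_equal(curve$probability[1],
               mean(psa$cost[, "pemigatinib"] < psa$cost[, "mfolfox"]))
  # two-strategy probabilities sum to one (ties to the intervention)
  p_int <- prob_ce(psa, "pemigatinib", "mfolfox", 97048)
  p_cmp <- mean(97048 * (psa$qaly[, "mfolfox"] - psa$qaly[, "pemigatinib"]) -
                  (psa$cost[, "mfolfox"] - psa$cost[, "pemigatinib"]) > 0)
  expect_equal(p_int + p_cmp, 1)
})

test_that("toy CEAC and EVPI cases compute by hand", {
  # two iterations with INMB +1 and -1: probability one half
  psa <- fake_psa(cost = cbind(A = c(0, 2), B = c(0, 0)),
                  qaly = cbind(A = c(1, 1), B = c(0, 0)))
  expect_equal(prob_ce(psa, "A", "B", wtp = 1), 0.5)

  # NMB A = {10, 0}, B = {0, 10}: E[max] = 10, max(E) = 5, EVPI = 5
  psa2 <- fake_psa(cost = cbind(A = c(0, 0), B = c(0, 0)),
                   qaly = cbind(A = c(10, 0), B = c(0, 10)))
  expect_equal(evpi(psa2, wtp = 1), 5)

  # one strategy dominant in every iteration: EVPI exactly zero
  psa3 <- fake_psa(cost = cbind(A = c(1, 2), B = c(5, 6)),
                   qaly = cbind(A = c(3, 4), B = c(1, 2)))
  expect_equal(evpi(psa3, wtp = 1), 0)
})

test_that("EVPI is non-negative on a real PSA", {
  psa <- run_psa(base_cfg, n_iter = 100, seed = 11)
  expect_gte(evpi(psa, base_cfg$econ$wtp), 0)
  expect_gte(evpi(psa, base_cfg$econ$wtp, c("pemigatinib", "fu5lv")), 0)
})

test_that("normal PSA draws respect the positivity floor by redrawing", {
  d <- dist_normal(0.1, 1, floor = 1e-6)
  draws <- withr::with_seed(2, vapply(1:500, function(i) {
    psmcea:::draw_psa_dist(d, NA)$value
  }, numeric(1)))
  expect_true(all(draws > 0))
})
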