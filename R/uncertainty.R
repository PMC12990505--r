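#' Define one uncertain parameter
#'
#' @param name Display name.
#' @param paths One dotted config path or a list of paths the parameter
#'   writes to (several paths model a cost shared across arms).
#' @param base Base value.
#' @param low,high Deterministic sensitivity range (low <= base <= high).
#' @param dist PSA distribution: one of `dist_fixed()`, `dist_normal()`,
#'   `dist_gamma()`, `dist_beta()`, `dist_uniform()`.
#' @return A `psa_param` list.
#' @export
psa_param <- function(name, paths, base, low, high, dist = dist_fixed()) {
  if (!is.list(paths)) paths <- list(paths)
  stopifnot(low <= base + 1e-9, base <= high + 1e-9)
  structure(list(name = name, paths = paths, base = base,
                 low = low, high = high, dist = dist),
            class = "psa_param")
}

#' PSA distributions
#'
#' Small constructors describing the marginal distribution a parameter is
#' drawn from in probabilistic sensitivity analysis. Normal draws destined
#' for positive-only parameters are redrawn above `floor`.
#'
#' @param mean,sd,shape,rate,a,b,lo,hi Distribution parameters.
#' @param floor Lower truncation bound for normal draws.
#' @return A `psa_dist` list.
#' @export
dist_fixed <- function() structure(list(type = "fixed"), class = "psa_dist")

#' @rdname dist_fixed
#' @export
dist_normal <- function(mean, sd, floor = NULL) {
  structure(list(type = "normal", mean = mean, sd = sd, floor = floor),
            class = "psa_dist")
}

#' @rdname dist_fixed
#' @export
dist_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(type = "gamma", shape = shape, rate = rate),
            class = "psa_dist")
}

#' @rdname dist_fixed
#' @export
dist_beta <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(type = "beta", a = a, b = b), class = "psa_dist")
}

#' @rdname dist_fixed
#' @export
dist_uniform <- function(lo, hi) {
  stopifnot(lo <= hi)
  structure(list(type = "uniform", lo = lo, hi = hi), class = "psa_dist")
}

# one draw; returns value and how many redraws the floor consumed
draw_psa_dist <- function(dist, base) {
  redraws <- 0L
  v <- switch(dist$type,
    "fixed" = base,
    "normal" = {
      x <- stats::rnorm(1, dist$mean, dist$sd)
      if (!is.null(dist$floor)) {
        while (x <= dist$floor) {
          x <- stats::rnorm(1, dist$mean, dist$sd)
          redraws <- redraws + 1L
          if (redraws > 1000L) stop("normal PSA draw cannot satisfy floor",
                                    call. = FALSE)
        }
      }
      x
    },
    "gamma" = stats::rgamma(1, shape = dist$shape, rate = dist$rate),
    "beta" = stats::rbeta(1, dist$a, dist$b),
    "uniform" = stats::runif(1, dist$lo, dist$hi),
    stop("unknown PSA distribution type: ", dist$type, call. = FALSE)
  )
  list(value = v, redraws = redraws)
}

apply_param <- function(config, param, value) {
  for (p in param$paths) config <- set_config_path(config, p, value)
  config
}

#' Default parameter space of the shipped base case
#'
#' The published deterministic ranges (95% confidence intervals where
#' reported, otherwise +/- 25%) and PSA distributions for every uncertain
#' parameter: survival scale/shape parameters (normal, truncated positive),
#' annual costs (uniform for the intervention's list price, gamma
#' otherwise; the chemotherapy non-medication and supportive-care costs are
#' shared across arms), utilities and the adverse-event disutility (beta),
#' with the administration-route disutility, adverse-event probabilities,
#' conversion factor and discount rate varied deterministically only.
#'
#' @param config A configuration shaped like [base_config()].
#' @return List of [psa_param()] entries.
#' @export
default_param_space <- function(config) {
  pp <- psa_param
  flo <- 1e-6
  list(
    pp("OS pemigatinib scale", "arms.pemigatinib.os.params.scale",
       18.387, 14.919, 22.661, dist_normal(18.387, 1.961, flo)),
    pp("OS pemigatinib shape", "arms.pemigatinib.os.params.shape",
       1.626, 1.384, 1.961, dist_normal(1.626, 0.156, flo)),
    pp("PFS pemigatinib meanlog", "arms.pemigatinib.pfs.params.meanlog",
       1.988, 1.792, 2.185, dist_normal(1.988, 0.100)),
    pp("PFS pemigatinib sdlog", "arms.pemigatinib.pfs.params.sdlog",
       0.989, 0.852, 1.149, dist_normal(0.989, 0.075, flo)),
    pp("OS mFOLFOX meanlog", "arms.mfolfox.os.params.meanlog",
       1.834, 1.642, 2.023, dist_normal(1.834, 0.098)),
    pp("OS mFOLFOX sdlog", "arms.mfolfox.os.params.sdlog",
       0.873, 0.742, 1.027, dist_normal(0.873, 0.072, flo)),
    pp("PFS mFOLFOX meanlog", "arms.mfolfox.pfs.params.meanlog",
       1.430, 1.265, 1.595, dist_normal(1.430, 0.084)),
    pp("PFS mFOLFOX sdlog", "arms.mfolfox.pfs.params.sdlog",
       0.754, 0.643, 0.885, dist_normal(0.754, 0.062, flo)),
    pp("OS 5-FU/LV meanlog", "arms.fu5lv.os.params.meanlog",
       1.794, 1.618, 1.970, dist_normal(1.794, 0.090)),
    pp("OS 5-FU/LV sdlog", "arms.fu5lv.os.params.sdlog",
       0.810, 0.691, 0.949, dist_normal(0.810, 0.066, flo)),
    pp("PFS 5-FU/LV meanlog", "arms.fu5lv.pfs.params.meanlog",
       0.809, 0.615, 1.004, dist_normal(0.809, 0.099)),
    pp("PFS 5-FU/LV sdlog", "arms.fu5lv.pfs.params.sdlog",
       0.9209, 0.791, 1.072, dist_normal(0.921, 0.072, flo)),
    pp("Medication cost pemigatinib", "arms.pemigatinib.cost_med_annual",
       97645, 73235, 122057, dist_uniform(73235, 122057)),
    pp("Medication cost mFOLFOX", "arms.mfolfox.cost_med_annual",
       13230, 9922, 16536, dist_gamma(41.39, 0.003115)),
    pp("Medication cost 5-FU/LV", "arms.fu5lv.cost_med_annual",
       5707, 4280, 7133, dist_gamma(36.83, 0.0065415)),
    pp("Non-medication cost pemigatinib", "arms.pemigatinib.cost_nonmed_annual",
       9361, 7020, 11701, dist_gamma(16.56, 0.001869)),
    pp("Non-medication cost chemotherapy",
       list("arms.mfolfox.cost_nonmed_annual", "arms.fu5lv.cost_nonmed_annual"),
       27512, 20634, 34389, dist_gamma(59.94, 0.0021805)),
    pp("Supportive care cost",
       list("arms.pemigatinib.cost_supportive_annual",
            "arms.mfolfox.cost_supportive_annual",
            "arms.fu5lv.cost_supportive_annual"),
       15978, 11983, 19972, dist_gamma(69.3, 0.004361)),
    pp("Utility PF", "econ.u_pf", 0.76, 0.57, 0.95, dist_beta(4.7, 1.5)),
    pp("Utility PD", "econ.u_pd", 0.68, 0.51, 0.85, dist_beta(29, 13.6)),
    pp("Disutility AE", "econ.du_ae", 0.16, 0.12, 0.20, dist_beta(36, 193)),
    pp("Disutility IV route", "econ.du_iv", 0.025, 0.019, 0.031, dist_fixed()),
    pp("AE probability pemigatinib", "arms.pemigatinib.p_ae",
       0.56, 0.42, 0.70, dist_fixed()),
    pp("AE probability mFOLFOX", "arms.mfolfox.p_ae",
       0.54, 0.405, 0.675, dist_fixed()),
    pp("AE probability 5-FU/LV", "arms.fu5lv.p_ae",
       0.18, 0.135, 0.225, dist_fixed()),
    pp("Conversion factor", "econ.conv_factor",
       0.9198, 0.9198, 0.9198, dist_uniform(0.9198, 0.9198)),
    pp("Discount rate", "econ.discount", 0.03, 0, 0.05, dist_fixed())
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each parameter to its low and high bound with everything else at
#' base, recomputes the ICER and INMB against the comparator, and sorts by
#' the absolute ICER swing. A bound at which the comparison leaves the
#' trade-off quadrant yields `NA` ICER and is flagged.
#'
#' @param config Full configuration.
#' @param space List of [psa_param()] entries.
#' @param intervention,comparator Arm names.
#' @return Data frame sorted by decreasing `|swing|`: parameter, bounds,
#'   `icer_low`, `icer_high`, `inmb_low`, `inmb_high`, `swing`, `flagged`.
#' @export
run_dsa <- function(config, space = default_param_space(config),
                    intervention = "pemigatinib", comparator = "mfolfox") {
  eval_at <- function(param, value) {
    cfg <- apply_param(config, param, value)
    cmp <- try(compare_config(cfg, intervention, comparator), silent = TRUE)
    if (inherits(cmp, "try-error")) {
      return(list(icer = NA_real_, inmb = NA_real_, failed = TRUE))
    }
    list(icer = cmp$icer, inmb = cmp$inmb, failed = FALSE)
  }
  rows <- lapply(space, function(p) {
    lo <- eval_at(p, p$low)
    hi <- eval_at(p, p$high)
    data.frame(parameter = p$name, low = p$low, high = p$high,
               icer_low = lo$icer, icer_high = hi$icer,
               inmb_low = lo$inmb, inmb_high = hi$inmb,
               swing = abs(hi$icer - lo$icer),
               flagged = lo$failed || hi$failed ||
                 is.na(lo$icer) || is.na(hi$icer))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$swing), -Inf, out$swing)), ]
  rownames(out) <- NULL
  out
}

#' Threshold value of a parameter at which the decision flips
#'
#' Bisection on one configuration value, solving INMB(value) = 0 at the
#' given willingness-to-pay (equivalently ICER = WTP in the trade-off
#' quadrant), to a relative tolerance of 1e-6 on the parameter.
#'
#' @param config Full configuration.
#' @param path Dotted config path of the parameter.
#' @param bracket Length-2 numeric search interval.
#' @param intervention,comparator Arm names.
#' @param wtp Willingness-to-pay (default: the configuration's).
#' @return The threshold value, or `NA` if INMB does not change sign on the
#'   bracket.
#' @export
threshold_search <- function(config, path, bracket,
                             intervention = "pemigatinib",
                             comparator = "mfolfox", wtp = config$econ$wtp) {
  f <- function(x) {
    cfg <- set_config_path(config, path, x)
    cmp <- compare_arms(run_arm(cfg, intervention), run_arm(cfg, comparator),
                        wtp = wtp)
    cmp$inmb
  }
  lo <- min(bracket); hi <- max(bracket)
  f_lo <- f(lo); f_hi <- f(hi)
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi)) {
    return(NA_real_)
  }
  while ((hi - lo) > 1e-6 * max(abs(hi), abs(lo), 1)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (f_mid == 0) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: each iteration draws every parameter
#' independently from its PSA distribution, applies the joint draw to the
#' configuration, and evaluates the full model for every arm. Reproducible
#' under the seed.
#'
#' @param config Full configuration.
#' @param space List of [psa_param()] entries.
#' @param n_iter Number of iterations (>= 1).
#' @param seed Integer seed.
#' @param arms Arm names to evaluate.
#' @return A `psa_result`: matrices `cost`, `qaly`, `ly` (iterations x
#'   arms), `n_iter`, `seed`, `n_redraws`.
#' @export
run_psa <- function(config, space = default_param_space(config),
                    n_iter = 1000, seed = 1L, arms = names(config$arms)) {
  stopifnot(n_iter >= 1)
  nm <- arms
  cost <- qaly <- ly <- matrix(NA_real_, n_iter, length(nm),
                               dimnames = list(NULL, nm))
  n_redraws <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      cfg <- config
      for (p in space) {
        dr <- draw_psa_dist(p$dist, p$base)
        n_redraws <- n_redraws + dr$redraws
        cfg <- apply_param(cfg, p, dr$value)
      }
      for (a in nm) {
        res <- run_arm(cfg, a)
        cost[it, a] <- res$totals$cost_total
        qaly[it, a] <- res$totals$qaly
        ly[it, a] <- res$totals$ly
      }
    }
  })
  structure(list(cost = cost, qaly = qaly, ly = ly, n_iter = n_iter,
                 seed = seed, arms = nm, n_redraws = n_redraws),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, arms: %s (seed %d, %d redraws)\n",
              x$n_iter, paste(x$arms, collapse = ", "), x$seed, x$n_redraws))
  invisible(x)
}

#' Per-iteration PSA draws as a long data frame
#' @param psa A `psa_result`.
#' @return Data frame: iteration, arm, cost, qaly, ly.
#' @export
psa_iterations <- function(psa) {
  do.call(rbind, lapply(psa$arms, function(a) {
    data.frame(iteration = seq_len(psa$n_iter), arm = a,
               cost = psa$cost[, a], qaly = psa$qaly[, a], ly = psa$ly[, a])
  }))
}

#' Probability that the intervention is cost-effective
#'
#' Fraction of PSA iterations with non-negative incremental net monetary
#' benefit at the threshold (ties count for the intervention).
#'
#' @param psa A `psa_result`.
#' @param intervention,comparator Arm names present in the PSA.
#' @param wtp Willingness-to-pay per unit effect.
#' @param effect `"qaly"` or `"ly"`.
#' @return Probability in `[0, 1]`.
#' @export
prob_ce <- function(psa, intervention, comparator, wtp,
                    effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  eff <- if (effect == "qaly") psa$qaly else psa$ly
  d_eff <- eff[, intervention] - eff[, comparator]
  d_cost <- psa$cost[, intervention] - psa$cost[, comparator]
  mean(wtp * d_eff - d_cost >= 0)
}

#' Cost-effectiveness acceptability curve
#' @inheritParams prob_ce
#' @param wtp_grid Vector of thresholds.
#' @return Data frame: `wtp`, `probability`.
#' @export
ceac <- function(psa, intervention, comparator, wtp_grid,
                 effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(w) {
               prob_ce(psa, intervention, comparator, w, effect)
             }, numeric(1)))
}

#' Per-person expected value of perfect information
#'
#' EVPI = E[max over strategies of NMB] - max over strategies of E[NMB],
#' over PSA iterations. Always non-negative; zero when one strategy is
#' preferred in every iteration.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay per unit effect.
#' @param arms Strategies considered (>= 2; default all in the PSA).
#' @param effect `"qaly"` or `"ly"`.
#' @return EVPI in USD per person.
#' @export
evpi <- function(psa, wtp, arms = psa$arms, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  stopifnot(length(arms) >= 2)
  eff <- if (effect == "qaly") psa$qaly else psa$ly
  nmb <- wtp * eff[, arms, drop = FALSE] - psa$cost[, arms, drop = FALSE]
  mean(apply(nmb, 1, max)) - max(colMeans(nmb))
}
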