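#' Define a scenario as sparse overrides of the base configuration
#'
#' Overrides are named by dotted config path (validated against the base
#' configuration when applied) with two conveniences: the name
#' `price_multiplier.<arm>` multiplies that arm's annual medication cost,
#' and `effect` ("qaly"/"ly") switches the effect measure of the reported
#' comparison.
#'
#' @param name Scenario label.
#' @param overrides Named list of path -> value substitutions.
#' @param effect Effect measure for the scenario's ICER/INMB.
#' @param psa Run a probabilistic sensitivity analysis for the scenario?
#' @param n_psa PSA iterations when `psa` is `TRUE`.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list(), effect = c("qaly", "ly"),
                          psa = FALSE, n_psa = 1000) {
  effect <- match.arg(effect)
  if (length(overrides) > 0 && is.null(names(overrides))) {
    stop("overrides must be a named list", call. = FALSE)
  }
  structure(list(name = name, overrides = overrides, effect = effect,
                 psa = psa, n_psa = n_psa),
            class = "scenario_spec")
}

#' Apply a scenario's overrides to a configuration
#' @param config Base configuration (never mutated).
#' @param spec A [scenario_spec()].
#' @return The overridden configuration.
#' @export
apply_scenario <- function(config, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  for (key in names(spec$overrides)) {
    value <- spec$overrides[[key]]
    if (startsWith(key, "price_multiplier.")) {
      arm <- sub("^price_multiplier\\.", "", key)
      path <- sprintf("arms.%s.cost_med_annual", arm)
      config <- set_config_path(config, path,
                                get_config_path(config, path) * value)
    } else {
      config <- set_config_path(config, key, value)
    }
  }
  config
}

#' Run one scenario against a comparator
#'
#' @param config Base configuration.
#' @param spec A [scenario_spec()].
#' @param intervention,comparator Arm names.
#' @param space Parameter space for the scenario's PSA (built on the
#'   overridden configuration when omitted).
#' @param seed Seed for the scenario's PSA.
#' @return One-row data frame: scenario, comparator, icer, inmb, d_cost,
#'   d_effect, plus `prob_ce` and `evpi` when a PSA was requested.
#' @export
run_scenario <- function(config, spec, intervention = "pemigatinib",
                         comparator = "mfolfox", space = NULL, seed = 1L) {
  cfg <- apply_scenario(config, spec)
  cmp <- compare_config(cfg, intervention, comparator, effect = spec$effect)
  out <- data.frame(scenario = spec$name, comparator = comparator,
                    effect = spec$effect, icer = cmp$icer, inmb = cmp$inmb,
                    d_cost = cmp$d_cost,
                    d_effect = if (spec$effect == "qaly") cmp$d_qaly
                               else cmp$d_ly,
                    dominance = cmp$dominance)
  if (isTRUE(spec$psa)) {
    if (is.null(space)) space <- default_param_space(cfg)
    psa <- run_psa(cfg, space, n_iter = spec$n_psa, seed = seed,
                   arms = c(intervention, comparator))
    out$prob_ce <- prob_ce(psa, intervention, comparator, cfg$econ$wtp,
                           effect = spec$effect)
    out$evpi <- evpi(psa, cfg$econ$wtp, effect = spec$effect)
  }
  out
}

#' Run a grid of scenarios across comparators
#'
#' Individual scenario failures are recorded in the `error` column and the
#' grid continues.
#'
#' @param config Base configuration.
#' @param specs List of [scenario_spec()]s.
#' @param intervention Arm name.
#' @param comparators Arm names compared against.
#' @param seed Seed passed to scenario PSAs.
#' @return Data frame with one row per scenario x comparator.
#' @export
run_scenario_grid <- function(config, specs, intervention = "pemigatinib",
                              comparators = c("mfolfox", "fu5lv"), seed = 1L) {
  rows <- list()
  for (spec in specs) {
    for (comp in comparators) {
      row <- tryCatch({
        r <- run_scenario(config, spec, intervention, comp, seed = seed)
        r$error <- NA_character_
        r
      }, error = function(e) {
        data.frame(scenario = spec$name, comparator = comp,
                   effect = spec$effect, icer = NA_real_, inmb = NA_real_,
                   d_cost = NA_real_, d_effect = NA_real_,
                   dominance = NA_character_, error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  base_cols <- c("scenario", "comparator", "effect", "icer", "inmb",
                 "d_cost", "d_effect", "dominance", "error")
  rows <- lapply(rows, function(r) {
    for (col in setdiff(base_cols, names(r))) r[[col]] <- NA
    extra <- setdiff(names(r), base_cols)
    r[, c(base_cols, extra), drop = FALSE]
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
    r[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The shipped scenario grid
#'
#' The thirteen structural scenarios of the worked example: base case,
#' life-year effectiveness, optimistic (log-logistic) and pessimistic
#' (Weibull proportional-hazards) extrapolations of the intervention's
#' curves (the latter also combined with a 10% price cut), time horizons of
#' 2/5/10/20/30 years, alternative adverse-event timing policies, and
#' event-specific adverse-event disutilities.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
base_scenarios <- function() {
  optimistic <- list(
    "arms.pemigatinib.os" = list(family = "log-logistic",
                                 params = list(scale = 18.387, shape = 1.626)),
    "arms.pemigatinib.pfs" = list(family = "log-logistic",
                                  params = list(scale = 7.512, shape = 1.736)))
  pessimistic <- list(
    "arms.pemigatinib.os" = list(family = "weibull-ph",
                                 params = list(scale = 0.019, shape = 1.194)),
    "arms.pemigatinib.pfs" = list(family = "weibull-ph",
                                  params = list(scale = 0.057, shape = 1.177)))
  specs <- list(
    scenario_spec("1.1 base case"),
    scenario_spec("1.2 life-year as effectiveness", effect = "ly"),
    scenario_spec("1.3 optimistic: log-logistic", optimistic),
    scenario_spec("1.4 pessimistic: Weibull PH", pessimistic),
    scenario_spec("1.5 pessimistic + 90% price",
                  c(pessimistic, list("price_multiplier.pemigatinib" = 0.9))),
    scenario_spec("1.6 horizon 2 years", list("econ.horizon_years" = 2)),
    scenario_spec("1.7 horizon 5 years", list("econ.horizon_years" = 5)),
    scenario_spec("1.8 horizon 10 years", list("econ.horizon_years" = 10)),
    scenario_spec("1.9 horizon 20 years", list("econ.horizon_years" = 20)),
    scenario_spec("1.10 horizon 30 years", list("econ.horizon_years" = 30)),
    scenario_spec("1.11 AE every cycle, first 6 months",
                  list("ae_policy" = "first-6-months")),
    scenario_spec("1.12 AE every cycle",
                  list("ae_policy" = "every-cycle")),
    scenario_spec("1.13 AE-specific disutility",
                  list("ae_granularity" = "event-specific"))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Template for a reassessment scenario on earlier trial data
#'
#' Rebuilds the model on the earlier (immature) efficacy reads of the
#' intervention and the 5-FU/LV comparator, as a starting point for
#' update-path analyses. The cost inputs of the original reference case
#' were reported in 2022 USD in a prior study and are not part of this
#' package's base case; the returned overrides therefore carry explicit
#' `NA` placeholders that must be filled before the scenario can run.
#'
#' @return A [scenario_spec()] with placeholder overrides.
#' @export
scenario2_template <- function() {
  scenario_spec(
    "2.1 reference case (placeholders)",
    list(
      "arms.pemigatinib.os" = list(family = "weibull",
                                   params = list(scale = 22.065,
                                                 shape = 1.536)),
      "arms.pemigatinib.pfs" = list(family = "log-normal",
                                    params = list(meanlog = 1.962,
                                                  sdlog = 0.971)),
      "arms.fu5lv.os" = list(family = "log-normal",
                             params = list(meanlog = 1.764, sdlog = 0.816)),
      "arms.fu5lv.pfs" = list(family = "log-normal",
                              params = list(meanlog = 0.8, sdlog = 1.067)),
      "econ.wtp" = 97908,
      # 2022-USD cost inputs of the prior reference case: fill before use
      "arms.pemigatinib.cost_med_annual" = NA_real_,
      "arms.mfolfox.cost_med_annual" = NA_real_,
      "arms.fu5lv.cost_med_annual" = NA_real_
    ))
}
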