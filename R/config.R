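#' Base-case model configuration
#'
#' Returns the full configuration of the shipped worked example: a
#' three-state partitioned survival model comparing an oral FGFR inhibitor
#' (pemigatinib) against two intravenous chemotherapy regimens (mFOLFOX and
#' 5-FU/LV) in advanced intrahepatic cholangiocarcinoma, from the Taiwanese
#' payer perspective in 2023 USD. Survival parameters are the published
#' base-case fits (times in months), costs are annual, the willingness-to-pay
#' threshold is three times GDP per capita, and the point-to-currency
#' conversion factor applies to non-medication and supportive-care costs
#' only.
#'
#' @return A nested list with components `econ`, `ae_policy`,
#'   `ae_granularity` and `arms`.
#' @export
base_config <- function() {
  ae_tbl <- function(event, prob, disutility) {
    data.frame(event = event, prob = prob, disutility = disutility)
  }
  list(
    econ = list(
      wtp = 97048,            # USD per QALY, 3x forecast 2023 GDP per capita
      discount = 0.03,        # annual
      horizon_years = 40,
      cycle_months = 1,
      u_pf = 0.76,
      u_pd = 0.68,
      du_ae = 0.16,           # grade >= 3 adverse events, first PF cycle
      du_iv = 0.025,          # per-cycle decrement for IV administration
      conv_factor = 0.9198,   # NHI point value for non-medication services
      testing_cost = 934,     # one-time genetic testing fee, USD
      include_testing = FALSE,
      currency = list(year = 2023, usd_twd = 31.35)
    ),
    ae_policy = "first-cycle",       # or "first-6-months", "every-cycle"
    ae_granularity = "aggregate",    # or "event-specific"
    arms = list(
      pemigatinib = list(
        label = "pemigatinib", route = "oral",
        pfs = list(family = "log-normal",
                   params = list(meanlog = 1.988, sdlog = 0.989)),
        os = list(family = "log-logistic",
                  params = list(scale = 18.387, shape = 1.626)),
        cost_med_annual = 97645,
        cost_nonmed_annual = 9361,
        cost_supportive_annual = 15978,
        p_ae = 0.56,
        ae_events = ae_tbl(
          c("stomatitis", "palmar-plantar erythrodysesthesia",
            "fatigue or lethargy", "hypophosphatemia"),
          c(0.083, 0.056, 0.019, 0.102),
          c(0.0375, 0.085, 0.085, 0))
      ),
      mfolfox = list(
        label = "mFOLFOX", route = "iv",
        pfs = list(family = "log-normal",
                   params = list(meanlog = 1.430, sdlog = 0.754)),
        os = list(family = "log-normal",
                  params = list(meanlog = 1.834, sdlog = 0.873)),
        cost_med_annual = 13230,
        cost_nonmed_annual = 27512,
        cost_supportive_annual = 15978,
        p_ae = 0.54,
        ae_events = ae_tbl(
          c("hypophosphatemia", "fatigue or lethargy", "neutropenia",
            "infection", "pain", "biliary event", "hypertension"),
          c(0.01, 0.19, 0.12, 0.18, 0.10, 0.19, 0.05),
          c(0, 0.085, 0.0607, 0.085, 0.069, 0.085, 0.03))
      ),
      fu5lv = list(
        label = "5-FU/LV", route = "iv",
        pfs = list(family = "log-normal",
                   params = list(meanlog = 0.809, sdlog = 0.9209)),
        os = list(family = "log-normal",
                  params = list(meanlog = 1.794, sdlog = 0.810)),
        cost_med_annual = 5707,
        cost_nonmed_annual = 27512,
        cost_supportive_annual = 15978,
        p_ae = 0.18,
        ae_events = ae_tbl(
          c("stomatitis", "palmar-plantar erythrodysesthesia",
            "hypophosphatemia"),
          c(0.05, 0.04, 0.07),
          c(0.0375, 0.085, 0))
      )
    )
  )
}

#' Read / write a model configuration (YAML or JSON)
#'
#' The on-disk format mirrors the structure of [base_config()]; the
#' extension decides the serializer.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config` returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # coerce AE tables back to data frames
  cfg$arms <- lapply(cfg$arms, function(a) {
    if (!is.null(a$ae_events) && !is.data.frame(a$ae_events)) {
      a$ae_events <- as.data.frame(a$ae_events)
    }
    a
  })
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' Get / set a value inside a configuration by dotted path
#'
#' `set_config_path` errors on paths that do not already exist, which keeps
#' scenario overrides honest.
#'
#' @param config Configuration list.
#' @param path Dotted path, e.g. `"arms.pemigatinib.cost_med_annual"`, or a
#'   character vector of components.
#' @return The value at the path / the modified configuration.
#' @export
get_config_path <- function(config, path) {
  keys <- if (length(path) == 1L) strsplit(path, ".", fixed = TRUE)[[1L]]
          else path
  node <- config
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node)) {
      stop(sprintf("unknown config path: %s", paste(keys, collapse = ".")),
           call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' @rdname get_config_path
#' @param value Replacement value.
#' @export
set_config_path <- function(config, path, value) {
  keys <- if (length(path) == 1L) strsplit(path, ".", fixed = TRUE)[[1L]]
          else path
  get_config_path(config, keys)  # existence check
  rec <- function(node, ks) {
    if (length(ks) == 1L) {
      node[[ks]] <- value
      return(node)
    }
    node[[ks[1L]]] <- rec(node[[ks[1L]]], ks[-1L])
    node
  }
  rec(config, keys)
}
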