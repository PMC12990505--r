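#' Parametric survival distributions
#'
#' Constructor for the parametric survival families used for extrapolation.
#' Eight parameterizations are supported (the Weibull appears in both its
#' accelerated-failure-time and proportional-hazards forms, which are distinct
#' parameter conventions of the same family):
#'
#' * `exponential`: `rate` (> 0), S(t) = exp(-rate t)
#' * `gamma`: `shape`, `rate` (> 0)
#' * `generalized-gamma`: `mu`, `sigma` (> 0), `Q`; Q = 0 reduces to log-normal
#' * `gompertz`: `shape` (any sign), `rate` (> 0);
#'   S(t) = exp(-(rate/shape)(e^(shape t) - 1))
#' * `weibull` (AFT): `shape`, `scale` (> 0); S(t) = exp(-(t/scale)^shape)
#' * `weibull-ph`: `shape`, `scale` (> 0); S(t) = exp(-scale t^shape)
#' * `log-logistic`: `shape`, `scale` (> 0); S(t) = 1/(1 + (t/scale)^shape)
#' * `log-normal`: `meanlog`, `sdlog` (> 0); S(t) = 1 - Phi((log t - meanlog)/sdlog)
#'
#' Times are in months throughout the package.
#'
#' @param family Family name (aliases such as "lognormal", "llogis",
#'   "weibull-aft", "gengamma" are accepted).
#' @param params Named list or vector of parameters in the family's
#'   canonical names above.
#' @return An object of class `parametric_survival`.
#' @examples
#' m <- parametric_survival("log-logistic", c(scale = 18.387, shape = 1.626))
#' surv_prob(m, c(0, 18.387))  # 1 and 0.5: the scale is the median
#' @export
parametric_survival <- function(family, params) {
  family <- canonical_family(family)
  params <- as.list(params)
  info <- family_info(family)
  missing <- setdiff(info$par_names, names(params))
  if (length(missing) > 0L) {
    stop(sprintf("family '%s' requires parameter(s): %s", family,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- params[info$par_names]
  vals <- unlist(params)
  if (any(!is.finite(vals))) {
    stop("parameters must be finite", call. = FALSE)
  }
  pos <- info$positive
  if (any(vals[pos] <= 0)) {
    bad <- info$par_names[pos][vals[pos] <= 0]
    stop(sprintf("parameter(s) %s of family '%s' must be positive",
                 paste(bad, collapse = ", "), family), call. = FALSE)
  }
  structure(list(family = family, params = params),
            class = "parametric_survival")
}

# Alias table: anything a config file might plausibly say.
FAMILY_ALIASES <- c(
  "exponential" = "exponential", "exp" = "exponential",
  "gamma" = "gamma",
  "generalized-gamma" = "generalized-gamma", "gengamma" = "generalized-gamma",
  "generalized gamma" = "generalized-gamma", "gen-gamma" = "generalized-gamma",
  "gompertz" = "gompertz",
  "weibull" = "weibull", "weibull-aft" = "weibull", "weibullaft" = "weibull",
  "weibull-ph" = "weibull-ph", "weibullph" = "weibull-ph",
  "weibull ph" = "weibull-ph",
  "log-logistic" = "log-logistic", "loglogistic" = "log-logistic",
  "llogis" = "log-logistic",
  "log-normal" = "log-normal", "lognormal" = "log-normal", "lnorm" = "log-normal"
)

canonical_family <- function(family) {
  stopifnot(is.character(family), length(family) == 1L)
  key <- tolower(trimws(family))
  if (!key %in% names(FAMILY_ALIASES)) {
    stop(sprintf("unknown survival family '%s' (supported: %s)", family,
                 paste(unique(FAMILY_ALIASES), collapse = ", ")),
         call. = FALSE)
  }
  unname(FAMILY_ALIASES[key])
}

#' @return names and positivity constraints of a family's parameters
#' @noRd
family_info <- function(family) {
  switch(family,
    "exponential"       = list(par_names = "rate", positive = TRUE),
    "gamma"             = list(par_names = c("shape", "rate"),
                               positive = c(TRUE, TRUE)),
    "generalized-gamma" = list(par_names = c("mu", "sigma", "Q"),
                               positive = c(FALSE, TRUE, FALSE)),
    "gompertz"          = list(par_names = c("shape", "rate"),
                               positive = c(FALSE, TRUE)),
    "weibull"           = list(par_names = c("shape", "scale"),
                               positive = c(TRUE, TRUE)),
    "weibull-ph"        = list(par_names = c("shape", "scale"),
                               positive = c(TRUE, TRUE)),
    "log-logistic"      = list(par_names = c("shape", "scale"),
                               positive = c(TRUE, TRUE)),
    "log-normal"        = list(par_names = c("meanlog", "sdlog"),
                               positive = c(FALSE, TRUE)),
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Supported survival family names
#' @return Character vector of canonical family names.
#' @export
survival_families <- function() {
  c("exponential", "gamma", "generalized-gamma", "gompertz",
    "weibull", "weibull-ph", "log-logistic", "log-normal")
}

#' Survival probability of a curve at given times
#'
#' Generic S(t) evaluator; methods exist for [parametric_survival()],
#' [km_curve()] and [hybrid_curve()] objects.
#'
#' @param x A survival-curve object.
#' @param t Vector of times in months, all >= 0.
#' @param ... Passed to methods.
#' @return Vector of survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(x, t, ...) UseMethod("surv_prob")

#' @export
surv_prob.parametric_survival <- function(x, t, ...) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  p <- x$params
  s <- switch(x$family,
    "exponential"       = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    "gamma"             = stats::pgamma(t, shape = p$shape, rate = p$rate,
                                        lower.tail = FALSE),
    "generalized-gamma" = flexsurv::pgengamma(t, mu = p$mu, sigma = p$sigma,
                                              Q = p$Q, lower.tail = FALSE),
    "gompertz"          = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate,
                                              lower.tail = FALSE),
    "weibull"           = stats::pweibull(t, shape = p$shape, scale = p$scale,
                                          lower.tail = FALSE),
    "weibull-ph"        = flexsurv::pweibullPH(t, shape = p$shape,
                                               scale = p$scale,
                                               lower.tail = FALSE),
    "log-logistic"      = flexsurv::pllogis(t, shape = p$shape, scale = p$scale,
                                            lower.tail = FALSE),
    "log-normal"        = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                        lower.tail = FALSE)
  )
  # S(0) = 1 exactly for every family
  s[t == 0] <- 1
  pmin(pmax(s, 0), 1)
}

#' Density of a parametric survival model
#' @param x A `parametric_survival` object.
#' @param t Times in months.
#' @param log Return log-density?
#' @return Density (or log-density) values.
#' @export
surv_density <- function(x, t, log = FALSE) {
  stopifnot(inherits(x, "parametric_survival"))
  p <- x$params
  switch(x$family,
    "exponential"       = stats::dexp(t, rate = p$rate, log = log),
    "gamma"             = stats::dgamma(t, shape = p$shape, rate = p$rate,
                                        log = log),
    "generalized-gamma" = flexsurv::dgengamma(t, mu = p$mu, sigma = p$sigma,
                                              Q = p$Q, log = log),
    "gompertz"          = flexsurv::dgompertz(t, shape = p$shape, rate = p$rate,
                                              log = log),
    "weibull"           = stats::dweibull(t, shape = p$shape, scale = p$scale,
                                          log = log),
    "weibull-ph"        = flexsurv::dweibullPH(t, shape = p$shape,
                                               scale = p$scale, log = log),
    "log-logistic"      = flexsurv::dllogis(t, shape = p$shape, scale = p$scale,
                                            log = log),
    "log-normal"        = stats::dlnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                        log = log)
  )
}

#' Hazard of a parametric survival model
#' @inheritParams surv_density
#' @return Hazard values h(t) = f(t)/S(t).
#' @export
surv_hazard <- function(x, t) {
  surv_density(x, t) / surv_prob(x, t)
}

#' Random event times from a parametric survival model
#' @param x A `parametric_survival` object.
#' @param n Number of draws.
#' @return Vector of `n` event times in months.
#' @export
surv_rand <- function(x, n) {
  stopifnot(inherits(x, "parametric_survival"))
  p <- x$params
  switch(x$family,
    "exponential"       = stats::rexp(n, rate = p$rate),
    "gamma"             = stats::rgamma(n, shape = p$shape, rate = p$rate),
    "generalized-gamma" = flexsurv::rgengamma(n, mu = p$mu, sigma = p$sigma,
                                              Q = p$Q),
    "gompertz"          = flexsurv::rgompertz(n, shape = p$shape, rate = p$rate),
    "weibull"           = stats::rweibull(n, shape = p$shape, scale = p$scale),
    "weibull-ph"        = flexsurv::rweibullPH(n, shape = p$shape,
                                               scale = p$scale),
    "log-logistic"      = flexsurv::rllogis(n, shape = p$shape, scale = p$scale),
    "log-normal"        = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
  )
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Restricted (optionally discounted) mean survival time
#'
#' Integrates S(t) (times a continuous-time discount factor when
#' `discount > 0`) over `[0, horizon]` by adaptive quadrature.
#'
#' @param model A curve accepted by [surv_prob()].
#' @param horizon Upper limit of integration, months.
#' @param discount Annual discount rate (default 0).
#' @param rel_tol Relative tolerance of the quadrature.
#' @return Mean (discounted) survival time in months.
#' @export
mean_survival <- function(model, horizon, discount = 0, rel_tol = 1e-6) {
  stopifnot(horizon > 0, discount >= 0)
  f <- function(t) surv_prob(model, t) * (1 + discount)^(-t / 12)
  # split the range so the quadrature resolves both the body and the far tail
  cuts <- unique(pmin(c(0, 12, 60, 240, horizon), horizon))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    total <- total + stats::integrate(f, cuts[i], cuts[i + 1L],
                                      rel.tol = rel_tol,
                                      subdivisions = 500L)$value
  }
  total
}
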