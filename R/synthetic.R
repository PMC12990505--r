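#' Specification of a simulated survival trial
#'
#' Describes a single-arm trial with known parametric ground truth and an
#' administrative censoring mechanism: subjects accrue uniformly over
#' `accrual_months`, follow-up stops at `cutoff_months` after trial start,
#' and subjects may drop out independently at exponential rate
#' `dropout_rate` per month.
#'
#' @param family,params Ground-truth distribution, see [parametric_survival()].
#' @param n Number of subjects (>= 1).
#' @param cutoff_months Administrative cutoff from trial start (> 0; may be
#'   `Inf` for complete follow-up).
#' @param accrual_months Uniform accrual window (default 0: all subjects enter
#'   at time 0). Must not exceed `cutoff_months`.
#' @param dropout_rate Exponential dropout rate per month (>= 0).
#' @param seed Integer RNG seed making [simulate_ipd()] deterministic.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(family, params, n, cutoff_months = Inf,
                     accrual_months = 0, dropout_rate = 0, seed = 1L) {
  model <- parametric_survival(family, params)
  stopifnot(n >= 1, cutoff_months > 0, accrual_months >= 0,
            dropout_rate >= 0, accrual_months <= cutoff_months)
  structure(list(model = model, n = as.integer(n),
                 cutoff_months = cutoff_months,
                 accrual_months = accrual_months,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_spec")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate right-censored individual patient data
#'
#' Draws event times from the spec's ground-truth family and censors each
#' subject at the minimum of independent dropout and administrative cutoff
#' (cutoff minus the subject's accrual offset). Deterministic under the
#' spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return A `pseudo_ipd` object (see [pseudo_ipd()]).
#' @examples
#' ipd <- simulate_ipd(sim_spec("log-logistic", c(scale = 18.387, shape = 1.626),
#'                              n = 100, cutoff_months = 50, seed = 7))
#' table(ipd$records$event)
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    event_t <- surv_rand(spec$model, spec$n)
    entry <- if (spec$accrual_months > 0) {
      stats::runif(spec$n, 0, spec$accrual_months)
    } else rep(0, spec$n)
    admin <- spec$cutoff_months - entry
    drop_t <- if (spec$dropout_rate > 0) {
      stats::rexp(spec$n, rate = spec$dropout_rate)
    } else rep(Inf, spec$n)
    cens_t <- pmin(admin, drop_t)
    time <- pmin(event_t, cens_t)
    event <- as.integer(event_t <= cens_t)
    # guard against zero observation times (probability zero for the
    # continuous families, but keeps downstream log-likelihoods finite)
    time <- pmax(time, .Machine$double.eps)
    pseudo_ipd(time, event, arm = spec$model$family)
  })
}

#' Pseudo individual-patient data
#'
#' A minimal container for (time, event) survival records.
#'
#' @param time Positive, finite observation times in months.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param arm Arm label.
#' @return An object of class `pseudo_ipd` with a `records` data frame.
#' @export
pseudo_ipd <- function(time, event, arm = "arm") {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  structure(list(records = data.frame(time = as.numeric(time),
                                      event = as.integer(event)),
                 arm = arm),
            class = "pseudo_ipd")
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat(sprintf("<pseudo_ipd> arm '%s': %d records, %d events\n",
              x$arm, nrow(x$records), sum(x$records$event)))
  invisible(x)
}

#' Write / read pseudo-IPD as CSV (columns: time, event)
#' @param ipd A `pseudo_ipd` object.
#' @param path File path.
#' @return `read_ipd_csv` returns a `pseudo_ipd`; `write_ipd_csv` its path,
#'   invisibly.
#' @export
write_ipd_csv <- function(ipd, path) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  utils::write.csv(ipd$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @param arm Arm label for the read records.
#' @export
read_ipd_csv <- function(path, arm = "arm") {
  d <- utils::read.csv(path)
  pseudo_ipd(d$time, d$event, arm = arm)
}

#' Kaplan-Meier (product-limit) curve of pseudo-IPD
#'
#' Thin wrapper around [survival::survfit()] that keeps the observation
#' times so the true at-risk process can be read off at any time point.
#'
#' @param ipd A `pseudo_ipd` object.
#' @return A `km_curve` object: step times, survival, at-risk counts.
#' @export
km_curve <- function(ipd) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  rec <- ipd$records
  if (nrow(rec) < 1) stop("empty input", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n0 = nrow(rec), obs_time = sort(rec$time),
                 max_time = max(rec$time)),
            class = "km_curve")
}

#' @export
surv_prob.km_curve <- function(x, t, ...) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (length(x$time) == 0L) return(rep(1, length(t)))
  f <- stats::stepfun(x$time, c(1, x$surv), right = FALSE)
  f(t)
}

#' Number at risk at given times
#' @param km A `km_curve`.
#' @param t Times in months.
#' @return Integer counts of subjects still under observation at `t-`.
#' @export
n_at_risk <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  vapply(t, function(u) sum(km$obs_time >= u), integer(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d event times, follow-up %.1f months\n",
              x$n0, sum(x$n_event > 0), x$max_time))
  invisible(x)
}

#' Digitized survival curve with number-at-risk table
#'
#' The container a plot digitizer would produce from a published figure:
#' ordered survival coordinates plus periodic at-risk counts.
#'
#' @param points Data frame with columns `time`, `surv`; first row must be
#'   (0, 1), times strictly increasing, survival non-increasing in `[0, 1]`.
#' @param risk_table Data frame with columns `time`, `n_risk`; counts
#'   non-increasing and non-negative.
#' @param total_events Optional total event count.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(points, risk_table, total_events = NULL) {
  stopifnot(is.data.frame(points), all(c("time", "surv") %in% names(points)),
            is.data.frame(risk_table),
            all(c("time", "n_risk") %in% names(risk_table)))
  if (nrow(points) < 1 || points$time[1] != 0 || points$surv[1] != 1) {
    stop("first digitized point must be (0, 1)", call. = FALSE)
  }
  if (any(diff(points$time) <= 0)) {
    stop("digitized times must be strictly increasing", call. = FALSE)
  }
  if (any(points$surv < 0 | points$surv > 1) || any(diff(points$surv) > 1e-12)) {
    stop("digitized survival must be non-increasing within [0, 1]",
         call. = FALSE)
  }
  if (any(risk_table$n_risk < 0) || any(diff(risk_table$n_risk) > 0)) {
    stop("risk-table counts must be non-increasing and non-negative",
         call. = FALSE)
  }
  structure(list(points = points[, c("time", "surv")],
                 risk_table = risk_table[, c("time", "n_risk")],
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %d points, %d risk rows%s\n",
              nrow(x$points), nrow(x$risk_table),
              if (is.null(x$total_events)) ""
              else sprintf(", %d total events", x$total_events)))
  invisible(x)
}

#' Emulate plot-digitizer output from a Kaplan-Meier curve
#'
#' Samples "click" coordinates on the step function (optionally perturbed by
#' additive uniform reading noise on the survival axis and re-monotonized by
#' isotonic regression) and reads the at-risk table off the true at-risk
#' process at regular interval starts.
#'
#' @param km A `km_curve`.
#' @param n_points Number of points to emit including (0, 1). Default: one per
#'   step plus the origin, which makes zero-noise digitization lossless.
#' @param risk_interval Spacing of risk-table rows in months.
#' @param noise Half-width of the uniform reading error on the survival axis
#'   (default 0).
#' @return A [digitized_curve()].
#' @export
digitize_km <- function(km, n_points = NULL, risk_interval = 6, noise = 0) {
  stopifnot(inherits(km, "km_curve"), risk_interval > 0, noise >= 0)
  steps <- km$time[km$n_event > 0]
  if (length(steps) == 0L) steps <- km$max_time
  if (is.null(n_points)) n_points <- length(steps) + 1L
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  picks <- if (n_points - 1L >= length(steps)) steps else {
    steps[unique(round(seq(1, length(steps), length.out = n_points - 1L)))]
  }
  s <- surv_prob(km, picks)
  if (noise > 0) {
    s <- s + stats::runif(length(s), -noise, noise)
    s <- pmin(pmax(s, 0), 1)
    # isotonic (non-increasing) repair: PAVA on the negated values
    s <- -stats::isoreg(picks, -s)$yf
  }
  s <- cummin(c(1, s))  # the origin pins the repair at S(0) = 1
  points <- data.frame(time = c(0, picks), surv = s)
  rt_times <- seq(0, by = risk_interval,
                  length.out = max(1L, ceiling(km$max_time / risk_interval)))
  rt_times <- rt_times[rt_times < km$max_time]
  if (length(rt_times) == 0L) rt_times <- 0
  risk_table <- data.frame(time = rt_times, n_risk = n_at_risk(km, rt_times))
  digitized_curve(points, risk_table, total_events = sum(km$n_event))
}

#' Write a digitized curve as two CSV files
#' @param curve A `digitized_curve`.
#' @param points_path,risk_path Output paths for the coordinates and the
#'   risk table.
#' @return Invisibly, the two paths.
#' @export
write_digitized_csv <- function(curve, points_path, risk_path) {
  stopifnot(inherits(curve, "digitized_curve"))
  utils::write.csv(curve$points, points_path, row.names = FALSE)
  utils::write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(c(points_path, risk_path))
}

#' @rdname write_digitized_csv
#' @param total_events Optional total event count attached on read.
#' @export
read_digitized_csv <- function(points_path, risk_path, total_events = NULL) {
  digitized_curve(utils::read.csv(points_path), utils::read.csv(risk_path),
                  total_events = total_events)
}
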