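#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Implements an iterative product-limit inversion of the kind used to
#' recover per-patient records from published Kaplan-Meier figures. Within
#' each number-at-risk interval it solves for the censoring count such that
#' (i) the implied product-limit steps match the digitized survival drops and
#' (ii) the implied number at risk at the next interval start matches the
#' published risk table. Censoring times are spread evenly within the
#' interval; non-integer event counts are serialised with
#' cumulative-remainder rounding so interval totals are conserved. If
#' `total_events` is supplied, a final calibration pass adjusts the last
#' interval to match it.
#'
#' If the digitized survival rises anywhere (reading noise), the curve is
#' first repaired to be non-increasing by isotonic regression.
#'
#' @param curve A [digitized_curve()].
#' @param total_events Optional integer; overrides `curve$total_events`.
#' @param arm Arm label for the reconstructed records.
#' @return A [pseudo_ipd()] with exactly as many records as the initial
#'   at-risk count.
#' @export
reconstruct_ipd <- function(curve, total_events = NULL, arm = "reconstructed") {
  stopifnot(inherits(curve, "digitized_curve"))
  if (is.null(total_events)) total_events <- curve$total_events
  pts <- curve$points
  # defensive isotonic repair (constructor enforces monotone input, but raw
  # digitizer exports read through read_digitized_csv may arrive noisy)
  if (any(diff(pts$surv) > 0)) {
    pts$surv <- cummin(pmin(pmax(-stats::isoreg(pts$time, -pts$surv)$yf, 0), 1))
  }
  rt <- curve$risk_table
  if (nrow(rt) < 1) stop("risk table needs at least one row", call. = FALSE)
  K <- nrow(pts)
  R <- nrow(rt)
  t <- pts$time
  S <- pts$surv
  # click index ranges per risk interval; interval R is open-ended
  bounds <- c(rt$time, Inf)
  lower <- vapply(seq_len(R), function(i) {
    idx <- which(t >= bounds[i] & t < bounds[i + 1L])
    if (length(idx)) min(idx) else NA_integer_
  }, integer(1))
  upper <- vapply(seq_len(R), function(i) {
    idx <- which(t >= bounds[i] & t < bounds[i + 1L])
    if (length(idx)) max(idx) else NA_integer_
  }, integer(1))

  d <- numeric(K)        # events assigned at each click
  cens_times <- numeric(0)
  n_cur <- rt$n_risk[1]  # running at-risk count
  km_cur <- 1            # running product-limit value
  s_prev <- 1            # digitized survival at the previous click

  # walk one interval with censoring count ncen; returns the state after.
  # d_override, when given, replaces the survival-implied event counts
  # (used by the +/-1 reconciliation below)
  walk <- function(i, ncen, n_in, km_in, s_in, d_override = NULL) {
    lo <- lower[i]; up <- upper[i]
    iv_start <- rt$time[i]
    iv_end <- if (i < R) rt$time[i + 1L] else max(t[K], rt$time[R])
    ct <- if (ncen > 0) {
      iv_start + (seq_len(ncen) - 0.5) / ncen * (iv_end - iv_start)
    } else numeric(0)
    dk <- numeric(0)
    ev_real_cum <- 0; ev_int_cum <- 0
    n <- n_in; km <- km_in; s_last <- s_in
    if (!is.na(lo)) {
      for (k in lo:up) {
        # censorings occurring before this click leave the risk set first
        cen_before <- sum(ct >= (if (k == lo) iv_start else t[k - 1L]) &
                            ct < t[k])
        n <- n - cen_before
        if (is.null(d_override)) {
          d_real <- if (km > 0 && n > 0) n * (1 - S[k] / km) else 0
          d_real <- max(0, d_real)
          ev_real_cum <- ev_real_cum + d_real
          d_int <- round(ev_real_cum) - ev_int_cum
          d_int <- max(0, min(d_int, n))
          ev_int_cum <- ev_int_cum + d_int
        } else {
          d_int <- max(0, min(d_override[k - lo + 1L], n))
        }
        if (d_int > 0) km <- km * (1 - d_int / n)
        n <- n - d_int
        dk <- c(dk, d_int)
        s_last <- S[k]
      }
      # censorings after the last click in the interval
      n <- n - sum(ct >= t[up] & ct <= iv_end)
    } else {
      n <- n - ncen
    }
    list(n_out = n, km = km, s_last = s_last, d = dk, cens_times = ct)
  }

  for (i in seq_len(R)) {
    if (i < R) {
      target <- rt$n_risk[i + 1L]
      ncen <- max(0, round(n_cur * (if (!is.na(lower[i + 1L]))
        S[lower[i + 1L]] else s_prev) / max(km_cur, 1e-12)) - target)
      ncen <- min(ncen, n_cur)
      res <- NULL
      best <- NULL
      for (iter in 1:40) {
        res <- walk(i, ncen, n_cur, km_cur, s_prev)
        gap <- res$n_out - target
        if (is.null(best) || abs(gap) < abs(best$gap)) {
          best <- list(res = res, gap = gap, ncen = ncen)
        }
        if (gap == 0) break
        ncen_new <- min(max(ncen + gap, 0), n_cur)
        if (ncen_new == ncen) break
        ncen <- ncen_new
      }
      res <- best$res
      if (best$gap != 0 && abs(best$gap) <= 2 && !is.na(lower[i])) {
        # integer event rounding can leave the implied risk set off by one
        # or two; absorb the remainder into the interval's event counts
        # (never beyond), starting from the last click
        d_adj <- res$d
        remaining <- best$gap
        for (j in rev(seq_along(d_adj))) {
          if (remaining == 0) break
          delta <- if (remaining > 0) remaining else -min(d_adj[j], -remaining)
          d_adj[j] <- d_adj[j] + delta
          remaining <- remaining - delta
        }
        if (remaining == 0) {
          res <- walk(i, best$ncen, n_cur, km_cur, s_prev, d_override = d_adj)
        }
      }
      if (res$n_out != target) {
        stop(structure(class = c("psmcea_inconsistent_curve", "error",
                                 "condition"),
                       list(message = sprintf(
                         paste0("risk table and survival curve are ",
                                "inconsistent in interval %d: implied %d at ",
                                "risk vs published %d"),
                         i, res$n_out, target),
                         call = NULL)))
      }
    } else {
      res <- walk(i, 0L, n_cur, km_cur, s_prev)
      if (!is.null(total_events)) {
        # calibration pass: absorb the event-count mismatch in the last click
        need <- total_events - (sum(d) + sum(res$d))
        if (length(res$d) > 0 && need != 0) {
          j <- length(res$d)
          adj <- max(0, min(res$d[j] + need, res$d[j] + res$n_out))
          res$n_out <- res$n_out + res$d[j] - adj
          res$d[j] <- adj
        }
      }
    }
    if (!is.na(lower[i])) d[lower[i]:upper[i]] <- res$d
    cens_times <- c(cens_times, res$cens_times)
    n_cur <- res$n_out
    km_cur <- res$km
    s_prev <- res$s_last
  }

  times <- c(rep(t, times = round(d)), cens_times,
             rep(max(t[K], rt$time[R]), n_cur))
  events <- c(rep(1L, sum(round(d))), rep(0L, length(cens_times) + n_cur))
  times <- pmax(times, .Machine$double.eps)
  pseudo_ipd(times, events, arm = arm)
}

#' Compare an original Kaplan-Meier curve with a reconstruction
#'
#' @param original A `km_curve` (or any object accepted by [surv_prob()]).
#' @param reconstructed A `pseudo_ipd` or `km_curve`.
#' @return List with `sup_norm` (largest absolute survival difference on the
#'   union of step times within the shared follow-up), `median_diff`
#'   (difference of median survival times, months), and `event_diff`
#'   (reconstructed minus original event count, `NA` when either side does
#'   not carry counts).
#' @export
compare_km <- function(original, reconstructed) {
  km2 <- if (inherits(reconstructed, "pseudo_ipd")) km_curve(reconstructed)
         else reconstructed
  stopifnot(inherits(km2, "km_curve"))
  t_max <- min(max_time_of(original), km2$max_time)
  grid <- sort(unique(c(0, step_times_of(original), km2$time)))
  grid <- grid[grid <= t_max]
  s1 <- surv_prob(original, grid)
  s2 <- surv_prob(km2, grid)
  ev1 <- if (inherits(original, "km_curve")) sum(original$n_event) else NA
  list(sup_norm = max(abs(s1 - s2)),
       median_diff = median_surv_time(km2) - median_surv_time(original),
       event_diff = sum(km2$n_event) - ev1)
}

max_time_of <- function(x) {
  if (inherits(x, "km_curve")) x$max_time else Inf
}

step_times_of <- function(x) {
  if (inherits(x, "km_curve")) x$time else numeric(0)
}

#' Median survival time of a curve
#' @param x Object accepted by [surv_prob()].
#' @param upper Search bound in months for parametric curves.
#' @return First time at which S(t) <= 0.5, or `NA` if never reached.
#' @export
median_surv_time <- function(x, upper = 1200) {
  if (inherits(x, "km_curve")) {
    i <- which(x$surv <= 0.5)
    return(if (length(i)) x$time[min(i)] else NA_real_)
  }
  if (surv_prob(x, upper) > 0.5) return(NA_real_)
  stats::uniroot(function(t) surv_prob(x, t) - 0.5, c(1e-9, upper),
                 tol = 1e-8)$root
}
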