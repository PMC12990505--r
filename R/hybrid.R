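#' Hybrid Kaplan-Meier / parametric survival curve
#'
#' Joins an observed Kaplan-Meier segment on `[0, switch_time]` to a
#' parametric tail beyond it. The tail is rescaled so the hybrid is
#' continuous from the right at the handoff:
#' S(t) = KM(t) for t <= switch_time, and
#' S(t) = KM(switch_time) * S_tail(t) / S_tail(switch_time) otherwise.
#' With `switch_time = 0` (or `km = NULL`) the curve is purely parametric.
#'
#' @param km A [km_curve()] or `NULL`.
#' @param tail A [parametric_survival()].
#' @param switch_time Handoff time in months; must lie within the KM
#'   follow-up.
#' @return An object of class `hybrid_curve`, usable with [surv_prob()].
#' @export
hybrid_curve <- function(km, tail, switch_time = 0) {
  stopifnot(inherits(tail, "parametric_survival"), switch_time >= 0)
  if (switch_time == 0 || is.null(km)) {
    return(structure(list(km = NULL, tail = tail, switch_time = 0,
                          s_switch = 1, s_tail_switch = 1),
                     class = "hybrid_curve"))
  }
  stopifnot(inherits(km, "km_curve"))
  if (switch_time > km$max_time) {
    stop("switch_time must lie within the KM follow-up", call. = FALSE)
  }
  s_tail_switch <- surv_prob(tail, switch_time)
  if (s_tail_switch <= 0) {
    stop("parametric tail is zero at the switch time", call. = FALSE)
  }
  structure(list(km = km, tail = tail, switch_time = switch_time,
                 s_switch = surv_prob(km, switch_time),
                 s_tail_switch = s_tail_switch),
            class = "hybrid_curve")
}

#' @export
surv_prob.hybrid_curve <- function(x, t, ...) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (x$switch_time == 0) return(surv_prob(x$tail, t))
  s <- numeric(length(t))
  pre <- t <= x$switch_time
  if (any(pre)) s[pre] <- surv_prob(x$km, t[pre])
  if (any(!pre)) {
    s[!pre] <- x$s_switch * surv_prob(x$tail, t[!pre]) / x$s_tail_switch
  }
  pmin(pmax(s, 0), 1)
}

#' @export
print.hybrid_curve <- function(x, ...) {
  if (x$switch_time == 0) {
    cat("<hybrid_curve> pure parametric\n")
  } else {
    cat(sprintf("<hybrid_curve> KM to %.1f months (S = %.3f), %s tail\n",
                x$switch_time, x$s_switch, x$tail$family))
  }
  invisible(x)
}

# resolve a config curve spec into an object surv_prob() accepts
build_curve <- function(spec) {
  if (inherits(spec, c("parametric_survival", "hybrid_curve", "km_curve"))) {
    return(spec)
  }
  stopifnot(is.list(spec), !is.null(spec$family))
  tail <- parametric_survival(spec$family, spec$params)
  if (!is.null(spec$km) && !is.null(spec$switch_time) && spec$switch_time > 0) {
    hybrid_curve(spec$km, tail, spec$switch_time)
  } else {
    tail
  }
}
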