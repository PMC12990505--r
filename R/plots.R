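#' Plot helpers
#'
#' Lightweight ggplot2 figures for the standard decision-uncertainty
#' outputs. ggplot2 is suggested, not required; each function errors
#' cleanly when it is unavailable.
#'
#' @param ceac_df Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  need_ggplot2()
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ceac
#' @param psa A `psa_result`.
#' @param intervention,comparator Arm names.
#' @param wtp Threshold drawn as a reference slope.
#' @export
plot_ce_plane <- function(psa, intervention, comparator, wtp = NULL) {
  need_ggplot2()
  df <- data.frame(d_qaly = psa$qaly[, intervention] - psa$qaly[, comparator],
                   d_cost = psa$cost[, intervention] - psa$cost[, comparator])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' @rdname plot_ceac
#' @param tornado Output of [run_dsa()].
#' @param n_top Number of parameters displayed.
#' @export
plot_tornado <- function(tornado, n_top = 12) {
  need_ggplot2()
  df <- utils::head(tornado[!tornado$flagged, ], n_top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
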