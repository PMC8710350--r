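# Standard cost-effectiveness figures.

#' Cost-effectiveness plane with efficiency frontier
#'
#' Plots lifetime cost against DALYs averted for every strategy, connects
#' the frontier strategies, and marks the WTP threshold slope through the
#' optimal strategy.
#'
#' @param res A `cea_result` from [run_cea()] or [run_scenario()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(res) {
  wtp <- attr(res, "wtp")
  d <- as.data.frame(res)
  front <- d[d$dominance == "on_frontier", ]
  front <- front[order(front$dalys_averted), ]
  ggplot2::ggplot(d, ggplot2::aes(x = dalys_averted, y = cost)) +
    ggplot2::geom_line(data = front, linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = dominance), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = strategy),
                       vjust = -1, size = 3) +
    ggplot2::geom_abline(slope = wtp,
                         intercept = with(front[which.max(front$nmb), ],
                                          cost - wtp * dalys_averted),
                         linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "DALYs averted vs no adjuvant chemotherapy",
                  y = "Lifetime cost (I$, discounted)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df,
                  ggplot2::aes(x = wtp, y = probability,
                               colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (I$ per DALY averted)",
                  y = "Probability optimal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICER of the second frontier strategy (vs
#' the optimal) at each parameter's low and high value.
#'
#' @param dsa Output of [one_way_dsa()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa) {
  d <- dsa[!is.na(dsa$swing) & dsa$swing > 0, ]
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base_icer <- attr(dsa, "base_icer")
  ggplot2::ggplot(d, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low,
                                       xend = icer_high,
                                       yend = parameter),
                          linewidth = 5, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER, second frontier strategy vs optimal (I$/DALY averted)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("dalys_averted", "cost", "dominance", "strategy",
                         "wtp", "probability", "parameter", "icer_low",
                         "icer_high"))
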