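# ggplot2 methods for the result containers.

#' Plot state occupancy over time
#'
#' @param object A `tdm_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tdm_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("time_days", "dfs", "rd", "dead")],
    cols = c("dfs", "rd", "dead"),
    names_to = "state", values_to = "occupancy"
  )
  df$state <- factor(df$state, levels = c("dfs", "rd", "dead"),
                     labels = c("Disease-free", "Recurrent disease", "Dead"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_days / 365.25,
                                   .data$occupancy, colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years since treatment start", y = "State occupancy",
                  colour = NULL,
                  title = paste0("Cohort trace (",
                                 attr(object, "strategy") %||% "strategy", ")"))
}

#' Tornado plot of the one-way sensitivity analysis
#'
#' @param object A `tdm_dsa` tibble from [run_dsa()].
#' @param ... Unused.
#' @return A ggplot with incremental-cost bars per parameter endpoint.
#' @export
autoplot.tdm_dsa <- function(object, ...) {
  df <- as_tibble(object)
  df$parameter <- stats::reorder(df$parameter, df$swing)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter, x = .data$delta_cost,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "Incremental cost of monitoring (EUR)", y = NULL,
                  fill = "Endpoint", title = "One-way sensitivity analysis")
}

#' Cost-effectiveness plane of the probabilistic analysis
#'
#' @param object A `tdm_psa` from [run_psa()].
#' @param wtp Willingness-to-pay ray to draw (EUR/QALY); `NULL` for none.
#' @param ... Unused.
#' @return A ggplot of the incremental cost/effect cloud.
#' @export
autoplot.tdm_psa <- function(object, wtp = 20000, ...) {
  g <- ggplot2::ggplot(object$trials,
                       ggplot2::aes(.data$delta_qalys, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane")
  if (!is.null(wtp)) {
    g <- g + ggplot2::geom_abline(intercept = 0, slope = wtp,
                                  linetype = "dashed")
  }
  g
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `tdm_psa` from [run_psa()].
#' @return A ggplot of `P(cost-effective)` against willingness to pay.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}
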