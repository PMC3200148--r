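#' Plot one or several efficiency frontiers
#'
#' Budget (euro) against maximal attainable QALYs; for a scenario
#' comparison, one curve per scenario on the shared grid.
#'
#' @param x A `frontier` or a `scenario_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_frontiers <- function(x, ...) {
  if (inherits(x, "frontier")) {
    seg <- x$segments
    df <- tibble(budget = c(seg$b_lo, x$endpoint$budget),
                 qalys = c(seg$q_lo, x$endpoint$qalys))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$budget, y = .data$qalys)) +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "Budget (EUR, price level 2007)",
                      y = "Total health gains (QALY)",
                      title = "Cost-effectiveness efficiency frontier") +
        ggplot2::theme_minimal()
    )
  }
  if (inherits(x, "scenario_comparison")) {
    return(
      ggplot2::ggplot(x$values,
                      ggplot2::aes(x = .data$budget, y = .data$qalys,
                                   colour = .data$scenario,
                                   linetype = .data$scenario)) +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::labs(x = "Budget (EUR, price level 2007)",
                      y = "Total health gains (QALY)",
                      colour = NULL, linetype = NULL,
                      title = "Efficiency frontiers by scenario") +
        ggplot2::theme_minimal() +
        ggplot2::theme(legend.position = "bottom")
    )
  }
  stop("x must be a frontier or scenario_comparison", call. = FALSE)
}
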