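#' Plot methods for crankr result objects
#'
#' `autoplot.crank_metrics` shows the four robustness scores per community;
#' `autoplot.crank_prioritization` shows aggregate scores in rank order;
#' `autoplot.crank_benchmark` shows mean Spearman rho per ranking method
#' with 95% confidence intervals.
#'
#' @param object A crankr result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name crankr-autoplot
NULL

#' @rdname crankr-autoplot
#' @export
autoplot.crank_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object))[c("community", "r_l", "r_d", "r_b", "r_a")],
    cols = c("r_l", "r_d", "r_b", "r_a"),
    names_to = "metric", values_to = "score"
  )
  long$metric <- factor(long$metric, levels = c("r_l", "r_d", "r_b", "r_a"),
                        labels = c("likelihood", "density", "boundary",
                                   "allegiance"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$community, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "community", y = "robustness score") +
    ggplot2::theme_minimal()
}

#' @rdname crankr-autoplot
#' @export
autoplot.crank_prioritization <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::geom_text(ggplot2::aes(label = .data$community),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "rank (1 = highest priority)",
                  y = "aggregate score (weighted mean rank)") +
    ggplot2::theme_minimal()
}

#' @rdname crankr-autoplot
#' @export
autoplot.crank_benchmark <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  df$method <- stats::reorder(df$method, -df$mean_rho)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean_rho)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean Spearman ρ vs gold standard") +
    ggplot2::theme_minimal()
}
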