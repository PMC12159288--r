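#' @exportS3Method ggplot2::autoplot
autoplot.k_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  best <- attr(object, "best_k")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$log10_p)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$k == best, , drop = FALSE],
                        colour = "red", size = 3) +
    ggplot2::labs(
      x = "k-mer length",
      y = expression(log[10] ~ "Spearman p-value"),
      title = "Rank correlation with tree distance across k",
      subtitle = sprintf("best k = %d (red)", best)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an estimator against tree distance
#'
#' One point per genome pair; the expected pattern for a well-behaved
#' similarity estimator is a monotone decreasing cloud.
#'
#' @param pair_table A pair table from [make_pair_table()] containing a
#'   `tree_distance` column.
#' @param method Name of the estimator column to plot.
#' @return A ggplot object.
#' @export
plot_pair_correlation <- function(pair_table, method) {
  stopifnot(method %in% names(pair_table),
            "tree_distance" %in% names(pair_table))
  ggplot2::ggplot(pair_table,
                  ggplot2::aes(x = .data$tree_distance,
                               y = .data[[method]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "tree distance", y = method) +
    ggplot2::theme_minimal()
}
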