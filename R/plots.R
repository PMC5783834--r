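# ggplot2 graphics for the main result types.

#' Plot a degree distribution on log-log axes with its power-law fit
#'
#' @param net an igraph (or numeric degree vector)
#' @param fit overlay the least-squares power-law line
#' @return a ggplot
#' @export
plot_degree_distribution <- function(net, fit = TRUE) {
  pl <- powerlaw_fit(net)
  p <- ggplot2::ggplot(pl$data, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "node degree", y = "frequency",
                  subtitle = sprintf("slope = %.3f, R² = %.3f", pl$slope, pl$r_squared))
  if (fit) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                                  linewidth = 0.5, colour = "steelblue")
  }
  p
}

#' Plot lncRNA RWR scores by rank, highlighting significant lncRNAs
#'
#' @param object an `rwr_result`
#' @param alpha significance threshold for the highlight
#' @param top_n rank cut-off drawn as a vertical line
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.rwr_result <- function(object, alpha = 0.05, top_n = 20, ...) {
  tab <- object$lncrna |>
    mutate(significant = .data$p_emp < alpha)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rank, y = .data$score,
                                    colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = top_n + 0.5, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "score rank", y = "steady-state probability",
                  colour = sprintf("p < %g", alpha))
}

#' Heatmap of module expression ordered by the bidirectional clustering
#'
#' @param expr log2-scale expression tibble
#' @param submodules a `submodule_set` from [bicluster()]
#' @return a ggplot
#' @export
plot_submodule_heatmap <- function(expr, submodules) {
  x <- expr_matrix(expr)[submodules$feature_order, submodules$sample_order, drop = FALSE]
  z <- t(scale(t(x)))
  df <- as_tibble(z, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample", values_to = "z") |>
    mutate(feature_id = factor(.data$feature_id, levels = rev(submodules$feature_order)),
           sample = factor(.data$sample, levels = submodules$sample_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$feature_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
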