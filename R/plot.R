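#' Plot a trait network
#'
#' Fruchterman-Reingold layout (seeded, so plots are reproducible) with
#' nodes colored by parent trait and sized by standardized degree,
#' mirroring the usual presentation of trait co-occurrence networks.
#'
#' @param object a `trait_network`.
#' @param seed layout seed, default 42.
#' @param label label nodes with their trait level (default `TRUE`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot trait_network
#' @export
autoplot.trait_network <- function(object, seed = 42L, label = TRUE, ...) {
  g <- object$graph
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- node_degrees(object)
  layout <- tibble(
    node = igraph::V(g)$name,
    x = xy[, 1L], y = xy[, 2L]
  ) |>
    dplyr::left_join(nodes, by = "node")

  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0L) {
    seg <- object$edges |>
      dplyr::left_join(layout[, c("node", "x", "y")], by = c(from = "node")) |>
      dplyr::left_join(layout[, c("node", "x", "y")], by = c(to = "node"),
                       suffix = c("", "end"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linetype = .data$sign),
      color = "grey30", linewidth = 0.4
    )
  }
  p <- p + ggplot2::geom_point(
    data = layout,
    ggplot2::aes(x = .data$x, y = .data$y, color = .data$trait,
                 size = .data$standardized_degree)
  )
  if (label) {
    p <- p + ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$level),
      size = 3, vjust = -1.1
    )
  }
  p +
    ggplot2::scale_size_continuous(range = c(2, 8), limits = c(0, 1)) +
    ggplot2::labs(color = "trait", size = "standardized degree",
                  linetype = "association") +
    ggplot2::theme_void()
}

#' Plot bootstrap metric distributions for a two-group comparison
#'
#' Violin/boxplots of the per-replicate metric values of two bootstrap
#' ensembles, one facet per metric.
#'
#' @param a,b `bootstrap_ensemble` objects.
#' @param metrics metrics to show; default: all shared metric columns.
#' @param names group labels, default `c("A", "B")`.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(a, b, metrics = NULL, names = c("A", "B")) {
  stopifnot(inherits(a, "bootstrap_ensemble"), inherits(b, "bootstrap_ensemble"))
  long <- dplyr::bind_rows(setNames(list(a$metrics, b$metrics), names), .id = "group") |>
    tidyr::pivot_longer(-c("group", "replicate", "n_nodes", "n_edges"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  if (!is.null(metrics)) long <- dplyr::filter(long, .data$metric %in% metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, color = NA) +
    ggplot2::geom_boxplot(width = 0.2, outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "bootstrap metric value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
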