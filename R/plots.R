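# ggplot2 methods for the package's result objects.

#' @method autoplot signed_network
#' @export
autoplot.signed_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(node = object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- object$links |>
    left_join(pos, by = c(source = "node")) |>
    dplyr::rename(xs = "x", ys = "y") |>
    left_join(pos, by = c(target = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$x,
                   yend = .data$y, colour = .data$sign),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7
    ) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::scale_colour_manual(
      values = c(activation = "#2166ac", inhibition = "#b2182b")
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' @method autoplot activity_distribution
#' @export
autoplot.activity_distribution <- function(object, nodes = NULL, ...) {
  long <- activities_long(object)
  if (!is.null(nodes)) long <- long[long$node %in% nodes, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$activity)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~node, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "steady-state activity", y = "density",
                  title = paste("sample", object$sample))
}

#' @method autoplot dasc_result
#' @export
autoplot.dasc_result <- function(object, ...) {
  d <- tidy(object)
  d$neg_log_q <- -log10(pmax(d$q, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_median,
                                  y = .data$neg_log_q,
                                  colour = .data$called)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "min_effect"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "median activity difference (B - A)",
                  y = "-log10 q", colour = "called")
}

#' Per-group activity density plot
#'
#' Overlaid per-group density curves of the pooled steady-state activity
#' of selected nodes -- the standard way to show a differentially
#' activated component's distribution in the two phenotypes.
#'
#' @param grouped A `grouped_activities` object.
#' @param nodes Nodes to plot (default: first 6).
#' @return A ggplot object.
#' @export
plot_group_densities <- function(grouped, nodes = NULL) {
  stopifnot(inherits(grouped, "grouped_activities"))
  nodes <- nodes %||% head(rownames(grouped$pool_a), 6)
  long <- tidy(grouped)
  long <- long[long$node %in% nodes, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$activity,
                                     colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~node, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "steady-state activity", y = "density")
}
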