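#' Plot the per-tile coefficient track of a fitted gene model
#'
#' @param object A `gene_model`.
#' @param ... Unused.
#' @return A ggplot: tile index versus coefficient, active tiles
#'   highlighted.
#' @export
autoplot.gene_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tile, y = .data$estimate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$tile, yend = 0,
                                       colour = .data$active),
                          show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey70")) +
    ggplot2::labs(x = "tile", y = "coefficient",
                  title = object$gene_id,
                  subtitle = sprintf("alpha = %g, test Spearman rho = %.3f",
                                     object$alpha, object$test_spearman)) +
    ggplot2::theme_minimal()
}

#' Plot cell-type-specific Shapley z-scores along the window
#'
#' @param object A `shapley_table`.
#' @param ... Unused.
#' @return A ggplot faceted by cell type.
#' @export
autoplot.shapley_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$tile, y = .data$z)) +
    ggplot2::geom_point(size = 0.6, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = "tile", y = "Shapley z-score") +
    ggplot2::theme_minimal()
}

#' Plot a chromatin potential field
#'
#' @param object A `potential_field`.
#' @param grid_size When not NULL (default 30), arrows are first grid
#'   averaged with [grid_smooth()].
#' @param arrow_scale Multiplier on arrow length (default 1).
#' @param ... Unused.
#' @return A ggplot of the cell layout with overlay arrows.
#' @export
autoplot.potential_field <- function(object, grid_size = 30L,
                                     arrow_scale = 1, ...) {
  base <- ggplot2::ggplot(tibble::as_tibble(object),
                          ggplot2::aes(x = .data$x, y = .data$y))
  base <- if ("cell_type" %in% names(object)) {
    base + ggplot2::geom_point(ggplot2::aes(colour = .data$cell_type),
                               size = 0.5, alpha = 0.6)
  } else {
    base + ggplot2::geom_point(size = 0.5, alpha = 0.4, colour = "grey60")
  }
  arrows <- if (is.null(grid_size)) {
    tibble::tibble(x0 = object$x, y0 = object$y,
                   x1 = object$x + arrow_scale * object$dx,
                   y1 = object$y + arrow_scale * object$dy)
  } else {
    g <- grid_smooth(object, grid_size = grid_size)
    tibble::tibble(x0 = g$grid_x, y0 = g$grid_y,
                   x1 = g$grid_x + arrow_scale * g$dx,
                   y1 = g$grid_y + arrow_scale * g$dy)
  }
  base +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      linewidth = 0.3, inherit.aes = FALSE) +
    ggplot2::labs(x = "layout 1", y = "layout 2") +
    ggplot2::theme_minimal()
}

#' Plot per-unit enrichment with the bootstrap interval
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot of per-unit enrichment values with the overall mean
#'   and its bootstrap 95% interval.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- object$by_unit
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$unit,
                                                     .data$enrichment),
                                  y = .data$enrichment)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = object$mean, colour = "black") +
    ggplot2::geom_hline(yintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment",
                  title = sprintf("%s enrichment (mean %.2f)",
                                  object$kind, object$mean)) +
    ggplot2::theme_minimal()
}

#' Enrichment-recall curve plot
#'
#' @param curve Tibble from [enrichment_recall_curve()].
#' @return A ggplot of enrichment against the number of top tiles.
#' @export
plot_enrichment_recall <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_top_tiles,
                                      y = .data$enrichment)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "top-ranked gene-linked tiles", y = "enrichment") +
    ggplot2::theme_minimal()
}
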