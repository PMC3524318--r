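#' Plot expression trajectories
#'
#' @param object A `dton_expr`.
#' @param genes Optional subset of gene ids to show.
#' @param ... Unused.
#' @return A ggplot: one line per gene over time.
#' @method autoplot dton_expr
#' @export
autoplot.dton_expr <- function(object, genes = NULL, ...) {
  df <- tidy(object)
  if (!is.null(genes)) df <- dplyr::filter(df, .data$gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value, colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "time (hours)",
      y = switch(expr_stage(object),
        raw = "intensity", lcr = "LCR", standardized_lcr = "standardized LCR"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted spline curves over the observations
#'
#' @param object A `dton_spline_fits`.
#' @param table The `dton_expr` the fits came from (for the points).
#' @param genes Optional subset of gene ids.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot faceted by gene, with knot positions marked.
#' @method autoplot dton_spline_fits
#' @export
autoplot.dton_spline_fits <- function(object, table = NULL, genes = NULL,
                                      n_grid = 200, ...) {
  k <- object$knots
  ids <- names(object$fits)
  if (!is.null(genes)) ids <- intersect(ids, genes)
  grid <- seq(k$t_min, k$t_max, length.out = n_grid)
  curves <- purrr::map_dfr(ids, function(g) {
    tibble::tibble(gene = g, time = grid, value = evaluate_spline(object$fits[[g]], grid))
  })
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_vline(xintercept = c(k$K1, k$K2), linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time (hours)", y = "standardized LCR") +
    ggplot2::theme_minimal()
  if (!is.null(table)) {
    pts <- dplyr::filter(tidy(table), .data$gene %in% ids)
    p <- p + ggplot2::geom_point(data = pts, size = 1, colour = "grey30")
  }
  p
}

#' Plot the distribution of pairwise ordering evidence
#'
#' @param object A `dton_pair_scores` tibble.
#' @param ... Unused.
#' @return A ggplot histogram of `|delta|`.
#' @method autoplot dton_pair_scores
#' @export
autoplot.dton_pair_scores <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(is.finite(.data$delta))
  ggplot2::ggplot(df, ggplot2::aes(abs(.data$delta))) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = "log-likelihood difference |delta|",
      y = "gene pairs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a time-order network
#'
#' Nodes on a circle, directed edges as arrows with width proportional to
#' the ordering evidence. Intended for small (pruned) networks.
#'
#' @param object A `dton_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dton_network
#' @export
autoplot.dton_network <- function(object, ...) {
  n <- length(object$nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble::tibble(
    gene = object$nodes, x = cos(theta), y = sin(theta)
  )
  ed <- object$edges |>
    dplyr::left_join(layout, by = c(source = "gene")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(target = "gene")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$weight
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"), type = "closed"),
      colour = "grey50", alpha = 0.7
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(.data$x * 1.12, .data$y * 1.12, label = .data$gene),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("time-order network (%s)", object$variant))
}

#' Lollipop chart of incoming-edge hubs
#'
#' @param hubs A hub tibble from [find_incoming_edge_hubs()].
#' @return A ggplot of in-degree per hub gene.
#' @export
plot_hubs <- function(hubs) {
  df <- dplyr::mutate(hubs, gene = stats::reorder(.data$gene, .data$in_degree))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$in_degree, .data$gene))
  if ("trend" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$trend), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3, colour = "steelblue")
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = .data$in_degree, yend = .data$gene
    ), colour = "grey70") +
    ggplot2::labs(x = "incoming edges", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
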