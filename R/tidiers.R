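#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an expression table into long format
#'
#' @param x A `dton_expr`.
#' @param ... Unused.
#' @return A tibble `gene, time, value` (plus the stage as an attribute-free
#'   `stage` column for convenience).
#' @method tidy dton_expr
#' @export
tidy.dton_expr <- function(x, ...) {
  stage <- expr_stage(x)
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"gene", names_to = "time", values_to = "value") |>
    dplyr::mutate(time = as.numeric(.data$time), stage = stage)
}

#' Tidy spline fits: one row per gene and piece
#'
#' @param x A `dton_spline_fits`.
#' @param ... Unused.
#' @return A tibble `gene, piece, b0, b1, b2, b3`.
#' @method tidy dton_spline_fits
#' @export
tidy.dton_spline_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(
      gene = f$gene_id,
      piece = 1:3,
      b0 = c(f$beta1[1], f$beta2[1], f$beta3[1]),
      b1 = c(f$beta1[2], f$beta2[2], f$beta3[2]),
      b2 = c(f$beta1[3], f$beta2[3], f$beta3[3]),
      b3 = c(f$beta1[4], f$beta2[4], f$beta3[4])
    )
  })
}

#' Per-gene fit summaries
#'
#' @param x A `dton_spline_fits`.
#' @param ... Unused.
#' @return A tibble `gene, n, sigma2, loglik`.
#' @method glance dton_spline_fits
#' @export
glance.dton_spline_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(gene = f$gene_id, n = f$n, sigma2 = f$sigma2, loglik = f$loglik)
  })
}

#' Tidy a network into its edge list
#'
#' @param x A `dton_network`.
#' @param ... Unused.
#' @return The edge tibble `source, target, weight`.
#' @method tidy dton_network
#' @export
tidy.dton_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row network summary
#'
#' @param x A `dton_network`.
#' @param ... Unused.
#' @return A tibble `variant, n_nodes, n_edges, total_weight, n_hubs`.
#' @method glance dton_network
#' @export
glance.dton_network <- function(x, ...) {
  hubs <- find_incoming_edge_hubs(x, top = length(x$nodes))
  tibble::tibble(
    variant = x$variant,
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$weight),
    n_hubs = nrow(hubs)
  )
}
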