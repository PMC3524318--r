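#' Time-order networks
#'
#' A `dton_network` is a directed, weighted graph over genes: an edge
#' `u -> v` asserts that gene `v` responds later than gene `u`, with weight
#' the (positive) log-likelihood difference supporting that order. The
#' `variant` field records the construction stage: `full` (one edge per
#' scored pair), `thresholded`, `reduced` (after transitive reduction) or
#' `mwst` (maximum-weight spanning tree/forest).
#'
#' @param nodes Character vector of gene ids.
#' @param edges Tibble with columns `source`, `target`, `weight` (> 0).
#' @param variant One of `"full"`, `"thresholded"`, `"reduced"`, `"mwst"`.
#' @return A `dton_network`.
#' @export
new_network <- function(nodes, edges, variant) {
  variant <- match.arg(variant, c("full", "thresholded", "reduced", "mwst"))
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  if (nrow(edges) > 0 && any(edges$weight <= 0)) {
    rlang::abort("network edge weights must be positive")
  }
  key <- paste(pmin(edges$source, edges$target), pmax(edges$source, edges$target))
  if (anyDuplicated(key)) {
    rlang::abort("at most one directed edge per gene pair is allowed")
  }
  structure(
    list(nodes = as.character(nodes), edges = edges, variant = variant),
    class = "dton_network"
  )
}

#' @export
print.dton_network <- function(x, ...) {
  cat(sprintf(
    "# Time-order network (%s): %d genes, %d directed edges\n",
    x$variant, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Build the full time-order network from pair scores
#'
#' For each scored pair, only the direction with the positive log-likelihood
#' difference is kept as a directed edge with weight `|delta|`; the opposing
#' entry of the adjacency matrix is zero. Ties (`delta == 0`) contribute no
#' edge: neither order is supported.
#'
#' @param scores A `dton_pair_scores` tibble.
#' @return A `dton_network` with `variant = "full"`.
#' @export
build_adjacency <- function(scores) {
  stopifnot(is.data.frame(scores))
  key <- paste(
    pmin(scores$gene_a, scores$gene_b),
    pmax(scores$gene_a, scores$gene_b)
  )
  if (anyDuplicated(key)) rlang::abort("duplicate pair records in scores")
  nodes <- unique(c(scores$gene_a, scores$gene_b))
  kept <- scores |>
    dplyr::filter(.data$delta != 0) |>
    dplyr::transmute(
      source = ifelse(.data$delta > 0, .data$gene_a, .data$gene_b),
      target = ifelse(.data$delta > 0, .data$gene_b, .data$gene_a),
      weight = abs(.data$delta)
    )
  new_network(nodes, kept, "full")
}

#' Threshold a network at a weight quantile
#'
#' Removes edges whose weight falls below the given quantile of the kept
#' (positive) edge-weight distribution; the default, the median, halves the
#' edge count. Quantiles use the same linear-interpolation rule as the knot
#' placement.
#'
#' @param net A full `dton_network`.
#' @param quantile Fraction in `[0, 1)`.
#' @return A `dton_network` with `variant = "thresholded"`.
#' @export
threshold_network <- function(net, quantile = 0.5) {
  stopifnot(inherits(net, "dton_network"))
  if (net$variant != "full") rlang::abort("threshold_network() expects a full network")
  if (length(quantile) != 1 || quantile < 0 || quantile >= 1) {
    rlang::abort("`quantile` must be a single fraction in [0, 1)")
  }
  if (nrow(net$edges) == 0) {
    return(new_network(net$nodes, net$edges, "thresholded"))
  }
  cut <- unname(stats::quantile(net$edges$weight, probs = quantile, type = 7))
  new_network(
    net$nodes, dplyr::filter(net$edges, .data$weight >= cut),
    "thresholded"
  )
}

# adjacency (0/1) matrix in node order
edge_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    A[cbind(
      match(net$edges$source, net$nodes),
      match(net$edges$target, net$nodes)
    )] <- 1L
  }
  A
}

# boolean transitive closure by repeated squaring
reach_closure <- function(A) {
  R <- A > 0
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) {
      return(R)
    }
    R <- R2
  }
}

# is `to` reachable from `from` in the graph given by boolean adjacency B?
bfs_reaches <- function(B, from, to) {
  seen <- logical(nrow(B))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(B[frontier, , drop = FALSE]) > 0 & !seen)
    if (to %in% nxt) {
      return(TRUE)
    }
    if (length(nxt) == 0) {
      return(FALSE)
    }
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Remove redundant (transitively implied) edges
#'
#' When the network already asserts `A -> B` and `B -> C`, a direct
#' `A -> C` adds no ordering information and is removed. This generalizes
#' the length-2 rule to the full transitive reduction: an edge `(u, v)` is
#' removed exactly when `v` stays reachable from `u` through a path of
#' length >= 2 after deleting that edge. On an acyclic graph this is the
#' unique minimal subgraph with the same reachability. Edges lying inside a
#' directed cycle are never removed (the rule is ill-defined there) and a
#' warning is emitted.
#'
#' @param net A thresholded `dton_network`.
#' @return A `dton_network` with `variant = "reduced"`.
#' @export
remove_redundant_edges <- function(net) {
  stopifnot(inherits(net, "dton_network"))
  if (net$variant != "thresholded") {
    rlang::abort("remove_redundant_edges() expects a thresholded network")
  }
  if (nrow(net$edges) == 0) {
    return(new_network(net$nodes, net$edges, "reduced"))
  }
  A <- edge_matrix(net)
  R <- reach_closure(A)
  si <- match(net$edges$source, net$nodes)
  ti <- match(net$edges$target, net$nodes)
  in_cycle <- R[cbind(ti, si)] # v reaches back to u: edge lies on a cycle
  if (any(in_cycle)) {
    rlang::warn(sprintf(
      "%d edge(s) lie inside directed cycles and were kept as-is",
      sum(in_cycle)
    ))
  }
  # candidate screen: exists w with u -> w and w reaching v (w != v)
  Rstar <- R
  diag(Rstar) <- TRUE
  M <- A %*% (Rstar * 1)
  candidate <- M[cbind(si, ti)] > 1 # count includes the direct edge itself
  drop <- logical(nrow(net$edges))
  B <- A > 0
  for (e in which(candidate & !in_cycle)) {
    B[si[e], ti[e]] <- FALSE
    drop[e] <- bfs_reaches(B, si[e], ti[e])
    B[si[e], ti[e]] <- TRUE
  }
  new_network(net$nodes, net$edges[!drop, , drop = FALSE], "reduced")
}

#' Maximum-weight spanning tree of the time-order network
#'
#' At genome scale, thresholding either over-connects or shatters the graph;
#' the maximum-weight spanning tree keeps every gene connected through the
#' strongest ordering evidence. Edge direction is ignored while the tree is
#' selected (the weight `|delta|` measures the strength of the ordering
#' evidence irrespective of direction, via Prim's algorithm, run per
#' connected component so disconnected inputs yield a spanning forest) and
#' re-attached afterwards. Weight ties break lexicographically on the node
#' pair, so the result is deterministic.
#'
#' @param net A full `dton_network`.
#' @return A `dton_network` with `variant = "mwst"`.
#' @export
maximum_weight_spanning_tree <- function(net) {
  stopifnot(inherits(net, "dton_network"))
  if (net$variant != "full") {
    rlang::abort("maximum_weight_spanning_tree() expects a full network")
  }
  nodes <- net$nodes
  n <- length(nodes)
  if (n == 0 || nrow(net$edges) == 0) {
    return(new_network(nodes, net$edges[0, ], "mwst"))
  }
  si <- match(net$edges$source, nodes)
  ti <- match(net$edges$target, nodes)
  W <- matrix(NA_real_, n, n)
  W[cbind(si, ti)] <- net$edges$weight
  W[cbind(ti, si)] <- net$edges$weight
  in_tree <- logical(n)
  picked <- matrix(0L, 0, 2)
  remaining <- order(nodes) # seed components in lexicographic node order
  for (seed in remaining) {
    if (in_tree[seed]) next
    in_tree[seed] <- TRUE
    repeat {
      inside <- which(in_tree)
      outside <- which(!in_tree)
      if (length(outside) == 0) break
      Wcut <- W[inside, outside, drop = FALSE]
      if (all(is.na(Wcut))) break # component exhausted
      best <- max(Wcut, na.rm = TRUE)
      hits <- which(Wcut == best, arr.ind = TRUE)
      cand_u <- inside[hits[, 1]]
      cand_v <- outside[hits[, 2]]
      pair_key <- paste(
        pmin(nodes[cand_u], nodes[cand_v]),
        pmax(nodes[cand_u], nodes[cand_v])
      )
      pick <- order(pair_key)[1]
      u <- cand_u[pick]
      v <- cand_v[pick]
      in_tree[v] <- TRUE
      picked <- rbind(picked, c(u, v))
    }
  }
  # restore the original direction of each selected undirected edge
  key_all <- paste(pmin(si, ti), pmax(si, ti))
  key_pick <- paste(pmin(picked[, 1], picked[, 2]), pmax(picked[, 1], picked[, 2]))
  sel <- match(key_pick, key_all)
  edges <- net$edges[sel, , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  new_network(nodes, edges, "mwst")
}

#' Incoming-edge hubs: candidate late response genes
#'
#' A late response gene accumulates ordering evidence from many earlier
#' genes but precedes none, so it appears as a node with only incoming
#' edges; the more incoming edges, the later its response. Optionally
#' annotates each hub with its expression trend (see [classify_trend()]).
#'
#' @param net A `dton_network` (any variant).
#' @param top Maximum number of hubs to return.
#' @param fits Optional `dton_spline_fits` used to attach a `trend` column.
#' @return A tibble `gene, in_degree, out_degree` (plus `trend`,
#'   `late_mean` when `fits` is given), sorted by `in_degree` descending,
#'   ties broken by gene id.
#' @export
find_incoming_edge_hubs <- function(net, top = 10, fits = NULL) {
  stopifnot(inherits(net, "dton_network"))
  deg <- tibble::tibble(gene = net$nodes) |>
    dplyr::mutate(
      in_degree = vapply(
        .data$gene, function(g) sum(net$edges$target == g), integer(1),
        USE.NAMES = FALSE
      ),
      out_degree = vapply(
        .data$gene, function(g) sum(net$edges$source == g), integer(1),
        USE.NAMES = FALSE
      )
    )
  hubs <- deg |>
    dplyr::filter(.data$out_degree == 0, .data$in_degree >= 1) |>
    dplyr::arrange(dplyr::desc(.data$in_degree), .data$gene) |>
    utils::head(top)
  if (!is.null(fits)) {
    trend <- purrr::map(hubs$gene, function(g) classify_trend(fits$fits[[g]]))
    hubs$trend <- purrr::map_chr(trend, "trend")
    hubs$late_mean <- purrr::map_dbl(trend, "late_mean")
  }
  hubs
}

#' Classify a gene's late expression trend
#'
#' Over- vs under-expression is judged by the mean fitted LCR over the late
#' window `[K2, t_max]`, computed exactly as
#' `(F(t_max) - F(K2)) / (t_max - K2)` from the closed-form integral.
#'
#' @param fit A `dton_spline`.
#' @return A list with `trend` (`"overexpressed"` / `"underexpressed"`),
#'   `late_mean`, and `boundary` (`TRUE` when the mean is exactly zero, in
#'   which case `"underexpressed"` is reported with the flag set).
#' @export
classify_trend <- function(fit) {
  k <- fit$knots
  cc <- integrate_spline(fit)
  late_mean <- (evaluate_cumulative(cc, k$t_max) - cc$C2) / (k$t_max - k$K2)
  list(
    trend = if (late_mean > 0) "overexpressed" else "underexpressed",
    late_mean = late_mean,
    boundary = late_mean == 0
  )
}

#' Export a network
#'
#' @param net A `dton_network`.
#' @param format `"tsv"` (edge list, 12 significant digits), `"graphml"`, or
#'   `"dot"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("tsv", "graphml", "dot"), path) {
  stopifnot(inherits(net, "dton_network"))
  format <- match.arg(format)
  switch(format,
    tsv = {
      out <- net$edges
      out$weight <- signif(out$weight, 12)
      readr::write_tsv(out, path)
    },
    graphml = export_graphml(net, path),
    dot = export_dot(net, path)
  )
  invisible(path)
}

export_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  key <- xml2::xml_add_child(doc, "key",
    id = "w", `for` = "edge",
    attr.name = "weight", attr.type = "double"
  )
  graph <- xml2::xml_add_child(doc, "graph", id = "dton", edgedefault = "directed")
  for (nd in net$nodes) xml2::xml_add_child(graph, "node", id = nd)
  for (i in seq_len(nrow(net$edges))) {
    e <- xml2::xml_add_child(graph, "edge",
      source = net$edges$source[i], target = net$edges$target[i]
    )
    d <- xml2::xml_add_child(e, "data", key = "w")
    xml2::xml_text(d) <- format(net$edges$weight[i], digits = 12)
  }
  xml2::write_xml(doc, path)
}

export_dot <- function(net, path) {
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c(
    "digraph dton {",
    paste0("  ", q(net$nodes), ";"),
    sprintf(
      "  %s -> %s [weight=%s];",
      q(net$edges$source), q(net$edges$target),
      format(net$edges$weight, digits = 12)
    ),
    "}"
  )
  writeLines(lines, path)
}

#' Re-import a TSV edge list as a network
#'
#' @param path Path written by [export_network()] with `format = "tsv"`.
#' @param nodes Optional full node set (isolated nodes are absent from the
#'   edge list); defaults to the nodes appearing in edges.
#' @param variant Variant tag to attach.
#' @return A `dton_network`.
#' @export
import_network_tsv <- function(path, nodes = NULL, variant = "full") {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      weight = readr::col_double()
    ), progress = FALSE
  )
  if (is.null(nodes)) nodes <- unique(c(df$source, df$target))
  new_network(nodes, df, variant)
}
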