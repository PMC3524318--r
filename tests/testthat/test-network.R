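mk_scores <- function(df) {
  structure(tibble::as_tibble(df),
    class = c("dton_pair_scores", class(tibble::tibble()))
  )
}

net_from_edges <- function(edges, nodes = NULL, variant = "thresholded") {
  edges <- tibble::as_tibble(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  new_network(nodes, edges, variant)
}

test_that("adjacency keeps one directed edge per pair, none on ties", {
  sc <- mk_scores(tibble::tibble(
    gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
    ll_ab = c(5, 1, 2), ll_ba = c(3, 1, 5),
    delta = c(2, 0, -3),
    direction = c("A->B", "tie", "C->B")
  ))
  net <- build_adjacency(sc)
  expect_identical(net$variant, "full")
  expect_identical(nrow(net$edges), 2L)
  ab <- dplyr::filter(net$edges, .data$source == "A")
  expect_identical(ab$target, "B")
  expect_identical(ab$weight, 2)
  cb <- dplyr::filter(net$edges, .data$source == "C")
  expect_identical(cb$target, "B")
  expect_identical(cb$weight, 3)
  expect_true("C" %in% net$nodes)

  dup <- mk_scores(tibble::tibble(
    gene_a = c("A", "B"), gene_b = c("B", "A"),
    ll_ab = 1, ll_ba = 0, delta = 1, direction = "x"
  ))
  expect_error(build_adjacency(dup), "duplicate")

  # 12 genes, 66 tie-free scores -> 66 edges
  set.seed(71)
  idx <- utils::combn(12, 2)
  sc66 <- mk_scores(tibble::tibble(
    gene_a = sprintf("g%02d", idx[1, ]), gene_b = sprintf("g%02d", idx[2, ]),
    ll_ab = 0, ll_ba = 0, delta = runif(66, 0.1, 2), direction = "x"
  ))
  expect_identical(nrow(build_adjacency(sc66)$edges), 66L)
})

test_that("quantile thresholding keeps the heavy tail", {
  ed <- tibble::tibble(
    source = c("A", "B", "C", "D"), target = c("B", "C", "D", "E"),
    weight = c(1, 2, 3, 4)
  )
  net <- net_from_edges(ed, variant = "full")
  th <- threshold_network(net, 0.5) # median 2.5
  expect_setequal(th$edges$weight, c(3, 4))
  expect_identical(threshold_network(net, 0)$edges$weight, c(1, 2, 3, 4))
  expect_error(threshold_network(net, 1), "fraction")

  # monotone in the quantile; agrees with a brute-force sort-and-filter
  set.seed(72)
  idx <- utils::combn(10, 2)
  sc <- mk_scores(tibble::tibble(
    gene_a = sprintf("n%02d", idx[1, ]), gene_b = sprintf("n%02d", idx[2, ]),
    ll_ab = 0, ll_ba = 0, delta = rnorm(ncol(idx)), direction = "x"
  ))
  full <- build_adjacency(sc)
  prev <- Inf
  for (q in c(0, 0.25, 0.5, 0.9)) {
    th <- threshold_network(full, q)
    cut <- stats::quantile(full$edges$weight, q, type = 7)
    expect_setequal(th$edges$weight, full$edges$weight[full$edges$weight >= cut])
    expect_lte(nrow(th$edges), prev)
    prev <- nrow(th$edges)
  }
})

test_that("redundant-edge removal is exact transitive reduction on DAGs", {
  tri <- net_from_edges(tibble::tibble(
    source = c("A", "B", "A"), target = c("B", "C", "C"), weight = c(1, 1, 1)
  ))
  red <- remove_redundant_edges(tri)
  expect_setequal(paste(red$edges$source, red$edges$target), c("A B", "B C"))

  chain <- net_from_edges(tibble::tibble(
    source = c("A", "B"), target = c("B", "C"), weight = 1
  ))
  expect_identical(nrow(remove_redundant_edges(chain)$edges), 2L)

  set.seed(73)
  for (rep in 1:25) {
    A <- random_dag(8)
    if (sum(A) == 0) next
    idx <- which(A > 0, arr.ind = TRUE)
    nodes <- sprintf("n%d", 1:8)
    net <- net_from_edges(
      tibble::tibble(
        source = nodes[idx[, 1]], target = nodes[idx[, 2]],
        weight = runif(nrow(idx), 0.5, 2)
      ),
      nodes = nodes
    )
    red <- remove_redundant_edges(net)
    keep <- transitive_reduction_oracle(A)
    got <- matrix(FALSE, 8, 8)
    got[cbind(
      match(red$edges$source, nodes),
      match(red$edges$target, nodes)
    )] <- TRUE
    expect_identical(got, keep)
    # reachability is preserved
    expect_identical(warshall_closure(got * 1), warshall_closure(A))
  }
})

test_that("cycle edges survive reduction with a warning", {
  cyc <- net_from_edges(tibble::tibble(
    source = c("A", "B", "C", "A"), target = c("B", "C", "A", "D"),
    weight = 1
  ))
  expect_warning(red <- remove_redundant_edges(cyc), "cycle")
  expect_identical(nrow(red$edges), 4L)
})

test_that("Prim's MWST matches exhaustive enumeration and spans", {
  # triangle: drop the lightest edge
  tri <- net_from_edges(
    tibble::tibble(
      source = c("A", "B", "A"), target = c("B", "C", "C"),
      weight = c(3, 2, 1)
    ),
    variant = "full"
  )
  tree <- maximum_weight_spanning_tree(tri)
  expect_setequal(tree$edges$weight, c(3, 2))

  # equal-weight path graph is forced
  path <- net_from_edges(
    tibble::tibble(source = c("A", "B", "C"), target = c("B", "C", "D"), weight = 1),
    variant = "full"
  )
  expect_identical(nrow(maximum_weight_spanning_tree(path)$edges), 3L)

  set.seed(74)
  for (n in c(4L, 5L, 6L, 7L)) {
    nodes <- sprintf("n%d", seq_len(n))
    idx <- utils::combn(n, 2)
    w <- runif(ncol(idx), 0.1, 5)
    dirflip <- runif(ncol(idx)) < 0.5
    net <- net_from_edges(
      tibble::tibble(
        source = nodes[ifelse(dirflip, idx[2, ], idx[1, ])],
        target = nodes[ifelse(dirflip, idx[1, ], idx[2, ])],
        weight = w
      ),
      nodes = nodes, variant = "full"
    )
    tree <- maximum_weight_spanning_tree(net)
    expect_identical(nrow(tree$edges), n - 1L)
    W <- matrix(NA_real_, n, n)
    W[cbind(idx[1, ], idx[2, ])] <- w
    W[cbind(idx[2, ], idx[1, ])] <- w
    expect_equal(sum(tree$edges$weight), max_tree_weight_exhaustive(W),
      tolerance = 1e-9
    )
    # selected edges keep their original orientation
    key <- paste(net$edges$source, net$edges$target)
    expect_true(all(paste(tree$edges$source, tree$edges$target) %in% key))
  }

  # disconnected components yield a spanning forest
  forest_net <- net_from_edges(
    tibble::tibble(
      source = c("A", "B", "X"), target = c("B", "C", "Y"),
      weight = c(2, 1, 5)
    ),
    nodes = c("A", "B", "C", "X", "Y"), variant = "full"
  )
  forest <- maximum_weight_spanning_tree(forest_net)
  expect_identical(nrow(forest$edges), 3L) # (3 nodes - 1) + (2 nodes - 1)
})

test_that("MWST agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(75)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    nodes <- sprintf("n%d", seq_len(n))
    idx <- utils::combn(n, 2)
    w <- runif(ncol(idx), 0.1, 5)
    net <- net_from_edges(
      tibble::tibble(
        source = nodes[idx[1, ]], target = nodes[idx[2, ]], weight = w
      ),
      nodes = nodes, variant = "full"
    )
    tree <- maximum_weight_spanning_tree(net)
    g <- igraph::graph_from_data_frame(net$edges[, 1:2],
      directed = FALSE,
      vertices = nodes
    )
    mst <- igraph::mst(g, weights = -net$edges$weight)
    sel <- igraph::as_data_frame(mst)
    key_all <- paste(
      pmin(net$edges$source, net$edges$target),
      pmax(net$edges$source, net$edges$target)
    )
    key_sel <- paste(pmin(sel$from, sel$to), pmax(sel$from, sel$to))
    ig_total <- sum(net$edges$weight[match(key_sel, key_all)])
    expect_equal(sum(tree$edges$weight), ig_total, tolerance = 1e-9)
  }
})

test_that("incoming-edge hubs are pure sinks ranked by in-degree", {
  star <- net_from_edges(
    tibble::tibble(
      source = c("A", "B", "C", "D"), target = "Z", weight = 1
    ),
    variant = "mwst"
  )
  hubs <- find_incoming_edge_hubs(star)
  expect_identical(hubs$gene, "Z")
  expect_identical(hubs$in_degree, 4L)

  # a node with any outgoing edge is not a hub
  mixed <- net_from_edges(
    tibble::tibble(
      source = c("A", "B", "C", "D", "E", "M"),
      target = c("M", "M", "M", "M", "M", "X"),
      weight = 1
    ),
    variant = "mwst"
  )
  expect_false("M" %in% find_incoming_edge_hubs(mixed)$gene)

  empty <- new_network(character(0), tibble::tibble(
    source = character(0), target = character(0), weight = numeric(0)
  ), "full")
  expect_identical(nrow(find_incoming_edge_hubs(empty)), 0L)
})

test_that("trend classification follows the late-window mean sign", {
  k <- compute_knots(canonical_grid)
  rising <- fit_spline(seq(-1, 1, length.out = 12), canonical_grid, k)
  expect_identical(classify_trend(rising)$trend, "overexpressed")

  flat0 <- fit_spline(rep(0, 12), canonical_grid, k)
  tz <- classify_trend(flat0)
  expect_identical(tz$trend, "underexpressed")
  expect_true(tz$boundary)

  # sign agrees with numerically averaging the curve over [K2, 32]
  set.seed(76)
  for (rep in 1:10) {
    fit <- fit_spline(rnorm(12), canonical_grid, k)
    grid <- seq(k$K2, k$t_max, length.out = 100)
    expect_identical(
      classify_trend(fit)$trend,
      if (mean(evaluate_spline(fit, grid)) > 0) "overexpressed" else "underexpressed"
    )
  }
})

test_that("networks export to TSV (round-trip), GraphML and DOT", {
  net <- net_from_edges(
    tibble::tibble(
      source = c("A", "B", "C"), target = c("B", "C", "D"),
      weight = c(1.5, 2.25, pi)
    ),
    variant = "full"
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, "tsv", tsv)
  expect_identical(length(readLines(tsv)), 4L) # header + 3 edges
  back <- import_network_tsv(tsv, nodes = net$nodes)
  expect_equal(back$edges$weight, signif(net$edges$weight, 12))
  expect_identical(back$edges$source, net$edges$source)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  doc <- xml2::read_xml(gml) # parse fails if not well-formed
  expect_identical(xml2::xml_name(doc), "graphml")

  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, "dot", dot)
  txt <- readLines(dot)
  expect_identical(txt[1], "digraph dton {")
  expect_true(any(grepl("\"A\" -> \"B\"", txt)))
})
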