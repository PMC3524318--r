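# Shared fixtures and independent oracle implementations for the test suite.
# Every oracle here deliberately avoids the code path it checks.

canonical_grid <- c(0, 1, 2, 4, 6, 8, 12, 16, 20, 24, 28, 32)

make_raw_table <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                           times = canonical_grid[seq_len(ncol(m))],
                           stage = "raw") {
  colnames(m) <- as.character(times)
  as_expr_table(
    dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m)),
    stage = stage
  )
}

# --- constrained maximum likelihood, by numerical optimization -------------
# Maximizes the full 12-coefficient Gaussian likelihood subject to the 8
# equality constraints, by unconstrained BFGS over the constraint matrix's
# null space. Uses only the constraint matrix and raw piecewise evaluation.
constrained_mle_oracle <- function(y, times, knots) {
  A <- spline_constraint_matrix(knots)
  N <- svd(A, nu = 0, nv = 12)$v[, 9:12] # rank(A) = 8 -> 4-dim null space
  piece <- 1L + (times >= knots$K1) + (times >= knots$K2)
  predict_raw <- function(beta12) {
    vapply(seq_along(times), function(i) {
      b <- beta12[((piece[i] - 1) * 4 + 1):(piece[i] * 4)]
      b[1] + b[2] * times[i] + b[3] * times[i]^2 + b[4] * times[i]^3
    }, numeric(1))
  }
  # the prediction is linear in theta; build that map once from raw piecewise
  # evaluation of the null-space basis, and hand BFGS its exact gradient
  M <- vapply(1:4, function(j) predict_raw(N[, j]), numeric(length(times)))
  rss <- function(theta) sum((y - drop(M %*% theta))^2)
  grad <- function(theta) drop(-2 * crossprod(M, y - drop(M %*% theta)))
  fit <- stats::optim(rep(0, 4), rss, grad,
    method = "BFGS",
    control = list(maxit = 5000, reltol = 1e-16, abstol = 1e-16)
  )
  beta12 <- drop(N %*% fit$par)
  list(
    beta1 = beta12[1:4], beta2 = beta12[5:8], beta3 = beta12[9:12],
    fitted = predict_raw(beta12), rss = fit$value
  )
}

# --- exhaustive maximum spanning tree (Pruefer enumeration) ----------------
# Enumerates all n^(n-2) labelled spanning trees of the complete graph via
# Pruefer sequences, decoding all sequences in parallel, and returns the
# maximum total weight. W is a symmetric weight matrix with NA off-graph.
max_tree_weight_exhaustive <- function(W) {
  n <- nrow(W)
  stopifnot(n >= 2)
  if (n == 2) {
    return(W[1, 2])
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  S <- nrow(seqs)
  deg <- matrix(1L, S, n)
  for (j in seq_len(n - 2)) {
    idx <- cbind(seq_len(S), seqs[, j])
    deg[idx] <- deg[idx] + 1L
  }
  col_idx <- matrix(rep(seq_len(n), each = S), S, n)
  total <- numeric(S)
  for (i in seq_len(n - 2)) {
    idx <- col_idx
    idx[deg != 1L] <- n + 1L
    leaf <- max.col(-idx, ties.method = "first") # smallest degree-1 vertex
    total <- total + W[cbind(leaf, seqs[, i])]
    deg[cbind(seq_len(S), leaf)] <- 0L
    at <- cbind(seq_len(S), seqs[, i])
    deg[at] <- deg[at] - 1L
  }
  idx <- col_idx
  idx[deg != 1L] <- n + 1L
  u <- max.col(-idx, ties.method = "first")
  deg[cbind(seq_len(S), u)] <- 0L
  idx <- col_idx
  idx[deg != 1L] <- n + 1L
  v <- max.col(-idx, ties.method = "first")
  total <- total + W[cbind(u, v)]
  max(total)
}

# --- reachability / transitive reduction oracles ---------------------------
warshall_closure <- function(A) {
  n <- nrow(A)
  R <- A > 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (R[i, k]) R[i, ] <- R[i, ] | R[k, ]
    }
  }
  R
}

# brute force: edge redundant iff target still reachable after deleting it
transitive_reduction_oracle <- function(A) {
  keep <- A > 0
  edges <- which(A > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    B <- A
    B[edges[e, 1], edges[e, 2]] <- 0
    if (warshall_closure(B)[edges[e, 1], edges[e, 2]]) {
      keep[edges[e, 1], edges[e, 2]] <- FALSE
    }
  }
  keep
}

# random DAG adjacency on n nodes (edges respect a random topological order)
random_dag <- function(n, p = 0.35) {
  A <- matrix(0, n, n)
  ord <- sample(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) A[ord[i], ord[j]] <- 1
    }
  }
  A
}

# score one simulated pair through the spline -> integrate -> regress path
score_simulated_pair <- function(pr, knots) {
  grid <- pr$times
  fa <- fit_spline(pr$ya, grid, knots)
  fb <- fit_spline(pr$yb, grid, knots)
  Fa <- evaluate_cumulative(integrate_spline(fa), grid)
  Fb <- evaluate_cumulative(integrate_spline(fb), grid)
  score_pair(pr$ya, pr$yb, Fa, Fb)
}
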