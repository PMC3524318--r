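#' Integrated-ODE regression log-likelihood
#'
#' The time-order model for an ordered pair says the downstream gene's
#' trajectory is a linear combination of both genes' cumulative expression:
#' `y ~ 1 + F_a + F_b` (the integrated form of
#' \eqn{dy/dt = k_1 f_a + k_2 y}). This returns the Gaussian log-likelihood
#' of that regression at its MLE, with variance `RSS/n` — the same
#' convention as the spline fits, so likelihoods are comparable.
#'
#' @param y Observed trajectory (response).
#' @param Fa,Fb Cumulative expression of the two genes at the same times.
#' @return The maximized log-likelihood; `Inf` when the fit is numerically
#'   perfect (RSS ~ 0).
#' @export
pair_regression_loglik <- function(y, Fa, Fb) {
  n <- length(y)
  if (length(Fa) != n || length(Fb) != n) {
    rlang::abort("y, Fa and Fb must have equal length")
  }
  X <- cbind(1, Fa, Fb)
  qrX <- qr(X)
  if (qrX$rank < 3) {
    rlang::abort(paste0(
      "collinear predictors in pair regression: the two cumulative curves ",
      "(plus intercept) do not span 3 dimensions"
    ))
  }
  res <- qr.resid(qrX, y)
  gaussian_mle_loglik(sum(res^2), n, sum(y^2))
}

#' Score the time order of one gene pair
#'
#' Two regressions share the predictor block `(1, F_a, F_b)`:
#' regressing `y_b` on it scores the order a before b, regressing `y_a`
#' scores b before a. Their log-likelihood difference `delta` is the
#' evidence for a preceding b; its sign gives the inferred direction.
#' Two perfect fits (both `Inf`) are a tie.
#'
#' @param ya,yb Observed trajectories of genes a and b.
#' @param Fa,Fb Their cumulative expression at the observation times.
#' @param gene_a,gene_b Identifiers for the output record.
#' @return A one-row `dton_pair_scores` tibble with columns `gene_a`,
#'   `gene_b`, `ll_ab`, `ll_ba`, `delta`, `direction`.
#' @export
score_pair <- function(ya, yb, Fa, Fb, gene_a = "a", gene_b = "b") {
  ll_ab <- pair_regression_loglik(yb, Fa, Fb)
  ll_ba <- pair_regression_loglik(ya, Fa, Fb)
  delta <- pair_delta(ll_ab, ll_ba)
  new_pair_scores(tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    ll_ab = ll_ab, ll_ba = ll_ba, delta = delta,
    direction = pair_direction(delta, gene_a, gene_b)
  ))
}

pair_delta <- function(ll_ab, ll_ba) {
  if (is.infinite(ll_ab) && is.infinite(ll_ba)) {
    return(0)
  }
  ll_ab - ll_ba
}

pair_direction <- function(delta, gene_a, gene_b) {
  dplyr::case_when(
    delta > 0 ~ paste0(gene_a, "->", gene_b),
    delta < 0 ~ paste0(gene_b, "->", gene_a),
    TRUE ~ "tie"
  )
}

new_pair_scores <- function(df) {
  structure(df, class = c("dton_pair_scores", class(tibble::tibble())))
}

#' Score all gene pairs of a table
#'
#' Computes each gene's cumulative expression once, then scores every
#' unordered pair (`n(n-1)/2` records) in lexicographic order of gene index.
#'
#' @param table A standardized_lcr-stage `dton_expr`.
#' @param fits A `dton_spline_fits` covering every gene in `table`.
#' @return A `dton_pair_scores` tibble, one row per unordered pair.
#' @export
score_all_pairs <- function(table, fits) {
  assert_expr(table, "standardized_lcr")
  stopifnot(inherits(fits, "dton_spline_fits"))
  genes <- table$gene
  missing <- setdiff(genes, names(fits$fits))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "no spline fit for gene(s): ", paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  times <- expr_times(table)
  Y <- expr_matrix(table)
  Fm <- t(vapply(
    genes,
    function(g) evaluate_cumulative(integrate_spline(fits$fits[[g]]), times),
    numeric(length(times))
  ))
  n <- length(genes)
  npair <- n * (n - 1) / 2
  ia <- integer(npair)
  ib <- integer(npair)
  ll_ab <- numeric(npair)
  ll_ba <- numeric(npair)
  r <- 0L
  for (i in seq_len(n - 1)) {
    Fi <- Fm[i, ]
    yi <- Y[i, ]
    for (j in (i + 1):n) {
      r <- r + 1L
      X <- cbind(1, Fi, Fm[j, ])
      qrX <- qr(X)
      if (qrX$rank < 3) {
        rlang::abort(sprintf(
          "collinear cumulative curves for pair (%s, %s)", genes[i], genes[j]
        ))
      }
      res <- qr.resid(qrX, cbind(Y[j, ], yi))
      ll_ab[r] <- gaussian_mle_loglik(sum(res[, 1]^2), ncol(Y), sum(Y[j, ]^2))
      ll_ba[r] <- gaussian_mle_loglik(sum(res[, 2]^2), ncol(Y), sum(yi^2))
      ia[r] <- i
      ib[r] <- j
    }
  }
  delta <- ll_ab - ll_ba
  delta[is.infinite(ll_ab) & is.infinite(ll_ba)] <- 0
  new_pair_scores(tibble::tibble(
    gene_a = genes[ia], gene_b = genes[ib],
    ll_ab = ll_ab, ll_ba = ll_ba, delta = delta,
    direction = dplyr::case_when(
      delta > 0 ~ paste0(genes[ia], "->", genes[ib]),
      delta < 0 ~ paste0(genes[ib], "->", genes[ia]),
      TRUE ~ "tie"
    )
  ))
}

#' Read / write pair-score tables
#'
#' Tab-separated with the stable column order
#' `gene_a, gene_b, ll_ab, ll_ba, delta, direction`.
#'
#' @param scores A `dton_pair_scores` tibble.
#' @param path File path.
#' @return `path` invisibly; the reader returns a `dton_pair_scores`.
#' @export
write_pair_scores <- function(scores, path) {
  stopifnot(inherits(scores, "dton_pair_scores"))
  readr::write_tsv(scores, path)
  invisible(path)
}

#' @rdname write_pair_scores
#' @export
read_pair_scores <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      gene_a = readr::col_character(), gene_b = readr::col_character(),
      ll_ab = readr::col_double(), ll_ba = readr::col_double(),
      delta = readr::col_double(), direction = readr::col_character()
    ), progress = FALSE
  )
  new_pair_scores(df)
}
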