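#' Spline knots from sampling-time quantiles
#'
#' The three-piece natural cubic spline splits the observation window at two
#' knots placed at quantiles of the sampling times themselves (by default the
#' 33rd and 67th percentiles), so each piece covers roughly a third of the
#' sampling effort. Quantiles use the linear-interpolation rule
#' \eqn{h = 1 + (n-1)p} (R's default type 7), which on the canonical
#' 12-point grid 0,1,2,4,6,8,12,16,20,24,28,32 places the knots at
#' 5.333 h and 17.333 h.
#'
#' @param times Strictly increasing sampling times (hours), at least two.
#' @param probs Two ascending probabilities in `[0, 1]`.
#' @return A `dton_knots` list with elements `K1`, `K2`, `t_min`, `t_max`.
#' @examples
#' compute_knots(c(0, 1, 2, 4, 6, 8, 12, 16, 20, 24, 28, 32))
#' @export
compute_knots <- function(times, probs = c(1 / 3, 2 / 3)) {
  times <- sort(as.numeric(times))
  if (length(unique(times)) < 2) rlang::abort("need at least 2 distinct times")
  if (length(probs) != 2 || any(probs < 0) || any(probs > 1) || diff(probs) <= 0) {
    rlang::abort("`probs` must be two ascending fractions in [0, 1]")
  }
  ks <- unname(stats::quantile(times, probs = probs, type = 7))
  new_knots(ks[1], ks[2], min(times), max(times))
}

new_knots <- function(K1, K2, t_min, t_max) {
  if (!(t_min <= K1 && K1 < K2 && K2 <= t_max)) {
    rlang::abort("knots must satisfy t_min <= K1 < K2 <= t_max")
  }
  structure(list(K1 = K1, K2 = K2, t_min = t_min, t_max = t_max),
    class = "dton_knots"
  )
}

#' @export
print.dton_knots <- function(x, ...) {
  cat(sprintf(
    "Spline knots: K1 = %.4g, K2 = %.4g on [%g, %g] hours\n",
    x$K1, x$K2, x$t_min, x$t_max
  ))
  invisible(x)
}

# cubic c(b0,b1,b2,b3) evaluated at t; also derivatives
poly_eval <- function(b, t, deriv = 0) {
  switch(as.character(deriv),
    "0" = b[1] + b[2] * t + b[3] * t^2 + b[4] * t^3,
    "1" = b[2] + 2 * b[3] * t + 3 * b[4] * t^2,
    "2" = 2 * b[3] + 6 * b[4] * t,
    rlang::abort("deriv must be 0, 1 or 2")
  )
}

# Row of the linear constraint system for one condition on one piece:
# value/derivative of piece j at time t, as a 12-vector coefficient block.
constraint_row <- function(j, t, deriv) {
  row <- numeric(12)
  block <- (j - 1) * 4 + 1:4
  row[block] <- switch(as.character(deriv),
    "0" = c(1, t, t^2, t^3),
    "1" = c(0, 1, 2 * t, 3 * t^2),
    "2" = c(0, 0, 2, 6 * t)
  )
  row
}

#' The natural-spline constraint system
#'
#' The three cubic pieces carry 12 raw coefficients. Eight linear equality
#' constraints tie them together: value, first- and second-derivative
#' continuity at each knot (6 equations) and zero second derivative at both
#' ends of the window (the "natural" boundary conditions, 2 equations).
#' The system has rank 8, leaving exactly 4 free parameters — the middle
#' piece's coefficients are a convenient free set.
#'
#' @param knots A `dton_knots` object.
#' @return An 8 x 12 matrix `A` such that valid coefficient stacks
#'   `c(beta1, beta2, beta3)` are exactly the null space of `A`.
#' @export
spline_constraint_matrix <- function(knots) {
  k <- knots
  A <- rbind(
    constraint_row(1, k$K1, 0) - constraint_row(2, k$K1, 0),
    constraint_row(1, k$K1, 1) - constraint_row(2, k$K1, 1),
    constraint_row(1, k$K1, 2) - constraint_row(2, k$K1, 2),
    constraint_row(2, k$K2, 0) - constraint_row(3, k$K2, 0),
    constraint_row(2, k$K2, 1) - constraint_row(3, k$K2, 1),
    constraint_row(2, k$K2, 2) - constraint_row(3, k$K2, 2),
    constraint_row(1, k$t_min, 2),
    constraint_row(3, k$t_max, 2)
  )
  dimnames(A) <- list(
    c(
      "C0@K1", "C1@K1", "C2@K1", "C0@K2", "C1@K2", "C2@K2",
      "natural@t_min", "natural@t_max"
    ),
    paste0(
      rep(c("b1", "b2", "b3"), each = 4),
      rep(0:3, times = 3)
    )
  )
  A
}

#' Solve the outer spline pieces from the middle one
#'
#' Given the middle piece's four cubic coefficients, the first and third
#' pieces are uniquely determined: each must match the middle piece's value,
#' slope and curvature at its knot and have zero curvature at its outer
#' boundary — four linear equations for four unknowns per side.
#'
#' @param beta2 Length-4 coefficients `(b0, b1, b2, b3)` of the middle piece.
#' @param knots A `dton_knots` object.
#' @return A list with elements `beta1` and `beta3` (length-4 each).
#' @examples
#' k <- compute_knots(c(0, 1, 2, 4, 6, 8, 12, 16, 20, 24, 28, 32))
#' solve_outer_coefficients(c(0, 0, 1, 0), k) # middle piece t^2
#' @export
solve_outer_coefficients <- function(beta2, knots) {
  stopifnot(length(beta2) == 4)
  k <- knots
  if (!(k$t_min < k$K1 && k$K1 < k$K2 && k$K2 < k$t_max)) {
    rlang::abort("degenerate knots: need t_min < K1 < K2 < t_max")
  }
  side <- function(tk, t_end) {
    # rows: value, slope, curvature at the knot; curvature at the outer end
    M <- rbind(
      c(1, tk, tk^2, tk^3),
      c(0, 1, 2 * tk, 3 * tk^2),
      c(0, 0, 2, 6 * tk),
      c(0, 0, 2, 6 * t_end)
    )
    M
  }
  rhs1 <- c(
    poly_eval(beta2, k$K1, 0), poly_eval(beta2, k$K1, 1),
    poly_eval(beta2, k$K1, 2), 0
  )
  rhs3 <- c(
    poly_eval(beta2, k$K2, 0), poly_eval(beta2, k$K2, 1),
    poly_eval(beta2, k$K2, 2), 0
  )
  list(
    beta1 = drop(solve(side(k$K1, k$t_min), rhs1)),
    beta3 = drop(solve(side(k$K2, k$t_max), rhs3))
  )
}

#' Piece membership for a time point
#'
#' Half-open convention: piece 1 on `[t_min, K1)`, piece 2 on `[K1, K2)`,
#' piece 3 on `[K2, t_max]`. Continuity makes the boundary choice
#' value-irrelevant, but region bookkeeping must be fixed.
#'
#' @param t Time(s) in hours, within `[t_min, t_max]`.
#' @param knots A `dton_knots` object.
#' @return Integer piece indices in 1..3.
#' @export
spline_region <- function(t, knots) {
  if (any(t < knots$t_min | t > knots$t_max)) {
    rlang::abort(sprintf(
      "time out of range [%g, %g]", knots$t_min, knots$t_max
    ))
  }
  1L + (t >= knots$K1) + (t >= knots$K2)
}

# 4x4 maps from the free (middle) coefficients to each outer piece's
# coefficients; columns are solve_outer_coefficients() on the unit vectors.
outer_maps <- function(knots) {
  B1 <- matrix(0, 4, 4)
  B3 <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- numeric(4)
    e[j] <- 1
    sol <- solve_outer_coefficients(e, knots)
    B1[, j] <- sol$beta1
    B3[, j] <- sol$beta3
  }
  list(B1 = B1, B3 = B3)
}

#' Reduced design matrix of the constrained spline
#'
#' Because the outer pieces are linear functions of the middle piece's four
#' coefficients, the whole constrained spline is linear in those four free
#' parameters. This builds the n x 4 matrix `T*` whose row for time `t`
#' gives the fitted value as `row %*% beta2`: middle-region rows are exactly
#' `(1, t, t^2, t^3)`; outer-region rows are the corresponding outer-piece
#' polynomial composed with the knot-matching solve.
#'
#' @param times Observation times within `[t_min, t_max]`.
#' @param knots A `dton_knots` object.
#' @return A `length(times)` x 4 numeric matrix.
#' @export
build_design_matrix <- function(times, knots) {
  region <- spline_region(times, knots)
  maps <- outer_maps(knots)
  tt <- cbind(1, times, times^2, times^3)
  X <- matrix(NA_real_, length(times), 4)
  X[region == 2, ] <- tt[region == 2, , drop = FALSE]
  X[region == 1, ] <- tt[region == 1, , drop = FALSE] %*% maps$B1
  X[region == 3, ] <- tt[region == 3, , drop = FALSE] %*% maps$B3
  dimnames(X) <- list(NULL, c("b0", "b1", "b2", "b3"))
  X
}

# Gaussian log-likelihood at the MLE variance RSS/n. RSS numerically zero
# (relative to the response scale) is reported as a perfect fit: +Inf.
gaussian_mle_loglik <- function(rss, n, y_scale) {
  if (rss <= 1e-12 * max(1, y_scale)) {
    return(Inf)
  }
  sigma2 <- rss / n
  -(n / 2) * (log(2 * pi * sigma2) + 1)
}

#' Fit a constrained natural cubic spline to one trajectory
#'
#' Ordinary least squares on the reduced design matrix gives the
#' maximum-likelihood middle-piece coefficients; the outer pieces follow from
#' the continuity solve. The residual variance is the Gaussian MLE `RSS/n`
#' (not `RSS/(n-4)`), matching the convention used when spline and pairwise
#' regression log-likelihoods are compared downstream.
#'
#' @param y Observed (standardized LCR) values, one per time point.
#' @param times Observation times.
#' @param knots A `dton_knots` object.
#' @param gene_id Optional identifier stored on the fit.
#' @return A `dton_spline` with elements `gene_id`, `knots`,
#'   `beta1`, `beta2`, `beta3`, `sigma2`, `loglik`, `n`, `fitted`.
#' @export
fit_spline <- function(y, times, knots, gene_id = NA_character_) {
  y <- as.numeric(y)
  times <- as.numeric(times)
  if (length(y) != length(times)) rlang::abort("y and times differ in length")
  n <- length(y)
  if (n < 5) rlang::abort("need at least 5 time points to fit 4 parameters")
  X <- build_design_matrix(times, knots)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    rlang::abort("rank-deficient spline design matrix; times too degenerate")
  }
  beta2 <- drop(qr.coef(qrX, y))
  fitted <- drop(X %*% beta2)
  rss <- sum((y - fitted)^2)
  y_scale <- sum(y^2)
  perfect <- rss <= 1e-12 * max(1, y_scale)
  sigma2 <- if (perfect) 0 else rss / n
  loglik <- gaussian_mle_loglik(rss, n, y_scale)
  outer <- solve_outer_coefficients(beta2, knots)
  fit <- structure(
    list(
      gene_id = gene_id, knots = knots,
      beta1 = unname(outer$beta1), beta2 = unname(beta2),
      beta3 = unname(outer$beta3),
      sigma2 = sigma2, loglik = loglik, n = n, fitted = fitted
    ),
    class = "dton_spline"
  )
  validate_spline_fit(fit)
  fit
}

# continuity / natural-boundary invariants, relative tolerance 1e-8
validate_spline_fit <- function(fit, tol = 1e-8) {
  k <- fit$knots
  scale <- max(1, abs(unlist(fit[c("beta1", "beta2", "beta3")])))
  chk <- c(
    poly_eval(fit$beta1, k$K1, 0) - poly_eval(fit$beta2, k$K1, 0),
    poly_eval(fit$beta1, k$K1, 1) - poly_eval(fit$beta2, k$K1, 1),
    poly_eval(fit$beta1, k$K1, 2) - poly_eval(fit$beta2, k$K1, 2),
    poly_eval(fit$beta2, k$K2, 0) - poly_eval(fit$beta3, k$K2, 0),
    poly_eval(fit$beta2, k$K2, 1) - poly_eval(fit$beta3, k$K2, 1),
    poly_eval(fit$beta2, k$K2, 2) - poly_eval(fit$beta3, k$K2, 2),
    poly_eval(fit$beta1, k$t_min, 2),
    poly_eval(fit$beta3, k$t_max, 2)
  )
  if (any(abs(chk) > tol * scale * max(1, k$t_max^2))) {
    rlang::abort("spline fit violates continuity/natural-boundary constraints")
  }
  invisible(fit)
}

#' Evaluate a fitted spline
#'
#' @param fit A `dton_spline`.
#' @param t Times within the fitting window.
#' @return Fitted values at `t`.
#' @export
evaluate_spline <- function(fit, t) {
  region <- spline_region(t, fit$knots)
  betas <- list(fit$beta1, fit$beta2, fit$beta3)
  vapply(
    seq_along(t),
    function(i) poly_eval(betas[[region[i]]], t[i], 0),
    numeric(1)
  )
}

#' Spline log-likelihood for a trajectory
#'
#' Gaussian log-likelihood of `y` under the fitted spline at the MLE
#' variance `RSS/n`: \eqn{-(n/2)(\log(2\pi\hat\sigma^2) + 1)}. A residual
#' sum of squares indistinguishable from zero returns `Inf` (perfect fit).
#'
#' @param fit A `dton_spline`.
#' @param y Observations.
#' @param times Their times.
#' @return The log-likelihood.
#' @export
spline_loglik <- function(fit, y, times) {
  if (length(y) != length(times)) rlang::abort("y and times differ in length")
  res <- y - evaluate_spline(fit, times)
  gaussian_mle_loglik(sum(res^2), length(y), sum(y^2))
}

#' Fit splines to every gene in a table
#'
#' @param table A standardized_lcr-stage `dton_expr` (other stages allowed,
#'   with the usual caveat that the pairwise scoring assumes comparable
#'   response scales).
#' @param probs Knot quantile probabilities, used when `knots` is `NULL`.
#' @param knots Optional explicit `dton_knots`.
#' @return A `dton_spline_fits`: named list of `dton_spline` objects with the
#'   shared `knots` and `times` attached.
#' @export
fit_splines <- function(table, probs = c(1 / 3, 2 / 3), knots = NULL) {
  assert_expr(table)
  times <- expr_times(table)
  if (is.null(knots)) knots <- compute_knots(times, probs)
  m <- expr_matrix(table)
  fits <- lapply(seq_len(nrow(m)), function(i) {
    fit_spline(m[i, ], times, knots, gene_id = rownames(m)[i])
  })
  names(fits) <- rownames(m)
  structure(list(fits = fits, knots = knots, times = times),
    class = "dton_spline_fits"
  )
}

#' @export
print.dton_spline_fits <- function(x, ...) {
  cat(sprintf(
    "# %d natural cubic spline fits; knots at %.4g and %.4g hours\n",
    length(x$fits), x$knots$K1, x$knots$K2
  ))
  invisible(x)
}

#' @export
print.dton_spline <- function(x, ...) {
  cat(sprintf(
    "Natural cubic spline fit%s: n = %d, sigma2 = %.4g, loglik = %.4g\n",
    if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id),
    x$n, x$sigma2, x$loglik
  ))
  invisible(x)
}

#' Serialize / read spline fit collections
#'
#' Stored as structured JSON text: knots, times, and per gene the three
#' coefficient vectors, `sigma2` and `loglik`. The reader refits nothing:
#' it restores the objects and re-checks the continuity invariants.
#'
#' @param fits A `dton_spline_fits`.
#' @param path Output (input) path.
#' @return `path` invisibly; for the reader, a `dton_spline_fits`.
#' @export
write_spline_fits <- function(fits, path) {
  stopifnot(inherits(fits, "dton_spline_fits"))
  payload <- list(
    knots = unclass(fits$knots),
    times = fits$times,
    genes = lapply(fits$fits, function(f) {
      list(
        gene_id = f$gene_id, beta1 = f$beta1, beta2 = f$beta2,
        beta3 = f$beta3, sigma2 = f$sigma2, loglik = f$loglik, n = f$n,
        fitted = f$fitted
      )
    })
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_spline_fits
#' @export
read_spline_fits <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  knots <- do.call(new_knots, as.list(payload$knots))
  fits <- lapply(payload$genes, function(g) {
    ll <- g$loglik
    if (is.character(ll)) ll <- as.numeric(ll) # "Inf" round-trips as string
    fit <- structure(
      list(
        gene_id = g$gene_id, knots = knots,
        beta1 = as.numeric(g$beta1), beta2 = as.numeric(g$beta2),
        beta3 = as.numeric(g$beta3), sigma2 = g$sigma2, loglik = ll,
        n = g$n, fitted = as.numeric(g$fitted)
      ),
      class = "dton_spline"
    )
    validate_spline_fit(fit)
    fit
  })
  structure(
    list(fits = fits, knots = knots, times = as.numeric(payload$times)),
    class = "dton_spline_fits"
  )
}
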