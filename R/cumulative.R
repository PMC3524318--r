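#' Integrate a fitted spline in closed form
#'
#' The integrated-ODE regression needs each gene's cumulative expression
#' \eqn{F(t) = \int_{t_{min}}^{t} f(s)\,ds}. Each cubic piece integrates to a
#' quartic; the constants of integration are fixed by `F(t_min) = 0` and by
#' continuity at the knots, where the accumulated areas
#' `C1 = F(K1)` and `C2 = F(K2)` carry over to the next piece.
#'
#' @param fit A `dton_spline`.
#' @return A `dton_cumcurve`: `gene_id`, `knots`, a list of three length-5
#'   antiderivative coefficient vectors (constant first), and `C1`, `C2`.
#' @export
integrate_spline <- function(fit) {
  k <- fit$knots
  anti <- function(b) c(0, b[1], b[2] / 2, b[3] / 3, b[4] / 4)
  qeval <- function(a, t) a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3 + a[5] * t^4
  a1 <- anti(fit$beta1)
  a2 <- anti(fit$beta2)
  a3 <- anti(fit$beta3)
  a1[1] <- -qeval(a1, k$t_min) # F(t_min) = 0
  C1 <- qeval(a1, k$K1)
  a2[1] <- C1 - qeval(a2, k$K1)
  C2 <- qeval(a2, k$K2)
  a3[1] <- C2 - qeval(a3, k$K2)
  structure(
    list(
      gene_id = fit$gene_id, knots = k,
      coef = list(a1, a2, a3), C1 = C1, C2 = C2
    ),
    class = "dton_cumcurve"
  )
}

#' Evaluate a cumulative expression curve
#'
#' @param curve A `dton_cumcurve` from [integrate_spline()].
#' @param t Times within the window.
#' @return `F(t)` values.
#' @export
evaluate_cumulative <- function(curve, t) {
  region <- spline_region(t, curve$knots)
  vapply(seq_along(t), function(i) {
    a <- curve$coef[[region[i]]]
    ti <- t[i]
    a[1] + a[2] * ti + a[3] * ti^2 + a[4] * ti^3 + a[5] * ti^4
  }, numeric(1))
}

#' @export
print.dton_cumcurve <- function(x, ...) {
  cat(sprintf(
    "Cumulative expression curve%s: C1 = %.4g, C2 = %.4g\n",
    if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id), x$C1, x$C2
  ))
  invisible(x)
}
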