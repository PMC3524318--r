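canonical_knots <- compute_knots(canonical_grid)

test_that("knot quantiles reproduce the canonical placements", {
  expect_equal(canonical_knots$K1, 16 / 3, tolerance = 1e-12)
  expect_equal(canonical_knots$K2, 52 / 3, tolerance = 1e-12)
  expect_identical(c(canonical_knots$t_min, canonical_knots$t_max), c(0, 32))

  expect_equal(compute_knots(c(0, 10), probs = c(0.25, 0.5))$K2, 5)
  k01 <- compute_knots(canonical_grid, probs = c(0, 1))
  expect_identical(c(k01$K1, k01$K2), c(0, 32))
  expect_error(compute_knots(canonical_grid, probs = c(-0.1, 0.5)), "fractions")
})

test_that("the constraint system has rank 8, leaving 4 free coefficients", {
  A <- spline_constraint_matrix(canonical_knots)
  expect_identical(dim(A), c(8L, 12L))
  expect_identical(qr(A)$rank, 8L)
  # and not just on the canonical knots
  for (k in list(
    new_knots(2, 9, 0, 20), new_knots(-1, 0.5, -3, 4)
  )) {
    expect_identical(qr(spline_constraint_matrix(k))$rank, 8L)
  }
})

test_that("outer pieces solve the knot-matching system", {
  K1 <- canonical_knots$K1
  zero <- solve_outer_coefficients(c(0, 0, 0, 0), canonical_knots)
  expect_equal(zero$beta1, rep(0, 4))
  expect_equal(zero$beta3, rep(0, 4))

  # a globally linear middle piece extends to the same line
  lin <- solve_outer_coefficients(c(2, -0.3, 0, 0), canonical_knots)
  expect_equal(lin$beta1, c(2, -0.3, 0, 0), tolerance = 1e-12)
  expect_equal(lin$beta3, c(2, -0.3, 0, 0), tolerance = 1e-12)

  # middle piece t^2: first piece must be -K1^2/3 + K1 t + t^3/(3 K1)
  sq <- solve_outer_coefficients(c(0, 0, 1, 0), canonical_knots)
  expect_equal(sq$beta1, c(-K1^2 / 3, K1, 0, 1 / (3 * K1)), tolerance = 1e-10)

  expect_error(
    solve_outer_coefficients(c(1, 0, 0, 0), new_knots(0, 5, 0, 32)),
    "degenerate"
  )
})

test_that("the reduced design matrix has the analytic structure", {
  X <- build_design_matrix(canonical_grid, canonical_knots)
  expect_identical(dim(X), c(12L, 4L))
  # middle-region rows are the plain cubic basis
  mid <- canonical_grid >= canonical_knots$K1 & canonical_grid < canonical_knots$K2
  expect_equal(
    unname(X[mid, ]),
    unname(cbind(1, canonical_grid[mid], canonical_grid[mid]^2, canonical_grid[mid]^3))
  )
  expect_equal(unname(X[1, ]), c(1, 0, -canonical_knots$K1^2 / 3, 0), tolerance = 1e-10)
  # every row equals the outer-coefficient solve applied to unit vectors
  for (tt in c(0, 2, 20, 32)) {
    row <- vapply(1:4, function(j) {
      e <- numeric(4)
      e[j] <- 1
      sol <- solve_outer_coefficients(e, canonical_knots)
      b <- if (tt < canonical_knots$K1) sol$beta1 else sol$beta3
      b[1] + b[2] * tt + b[3] * tt^2 + b[4] * tt^3
    }, numeric(1))
    expect_equal(unname(X[match(tt, canonical_grid), ]), row, tolerance = 1e-10)
  }
  expect_error(build_design_matrix(c(0, 40), canonical_knots), "out of range")
})

test_that("noiseless and constant signals are recovered exactly", {
  X <- build_design_matrix(canonical_grid, canonical_knots)
  b <- c(1, -0.5, 0.03, 0.001)
  fit <- fit_spline(drop(X %*% b), canonical_grid, canonical_knots)
  expect_equal(fit$beta2, b, tolerance = 1e-9)
  expect_identical(fit$sigma2, 0)
  expect_identical(fit$loglik, Inf)

  cfit <- fit_spline(rep(2.5, 12), canonical_grid, canonical_knots)
  expect_equal(cfit$beta2, c(2.5, 0, 0, 0), tolerance = 1e-9)
  expect_equal(evaluate_spline(cfit, c(0, 7, 31)), rep(2.5, 3), tolerance = 1e-9)

  expect_error(fit_spline(1:4, c(0, 1, 2, 3), canonical_knots), "at least 5")
})

test_that("reduced-design OLS equals constrained full-likelihood maximization", {
  set.seed(52)
  for (rep in 1:5) {
    y <- rnorm(12)
    fit <- fit_spline(y, canonical_grid, canonical_knots)
    oracle <- constrained_mle_oracle(y, canonical_grid, canonical_knots)
    expect_lt(max(abs(fit$beta2 - oracle$beta2)), 1e-6)
    expect_lt(max(abs(fit$fitted - oracle$fitted)), 1e-6)
  }
})

test_that("fitted splines are C2 at the knots with natural boundaries", {
  set.seed(53)
  eps <- 1e-7
  for (rep in 1:20) {
    fit <- fit_spline(rnorm(12), canonical_grid, canonical_knots)
    for (K in c(fit$knots$K1, fit$knots$K2)) {
      expect_equal(
        evaluate_spline(fit, K - eps), evaluate_spline(fit, K + eps),
        tolerance = 1e-5
      )
    }
    # exact coefficient-level checks at 1e-8
    k <- fit$knots
    f <- function(b, t, d) {
      switch(d + 1,
        b[1] + b[2] * t + b[3] * t^2 + b[4] * t^3,
        b[2] + 2 * b[3] * t + 3 * b[4] * t^2,
        2 * b[3] + 6 * b[4] * t
      )
    }
    for (d in 0:2) {
      expect_equal(f(fit$beta1, k$K1, d), f(fit$beta2, k$K1, d), tolerance = 1e-8)
      expect_equal(f(fit$beta2, k$K2, d), f(fit$beta3, k$K2, d), tolerance = 1e-8)
    }
    expect_lt(abs(f(fit$beta1, k$t_min, 2)), 1e-8)
    expect_lt(abs(f(fit$beta3, k$t_max, 2)), 1e-8)
  }
})

test_that("evaluation at the design times reproduces the linear map", {
  set.seed(54)
  y <- rnorm(12)
  fit <- fit_spline(y, canonical_grid, canonical_knots)
  X <- build_design_matrix(canonical_grid, canonical_knots)
  expect_equal(
    evaluate_spline(fit, canonical_grid), drop(X %*% fit$beta2),
    tolerance = 1e-10
  )
})

test_that("spline log-likelihood matches the closed form and density sums", {
  # n = 12, sigma2 = 1 closed form
  expect_equal(
    -(12 / 2) * (log(2 * pi * 1) + 1),
    -17.0270,
    tolerance = 1e-4
  )
  set.seed(55)
  y <- rnorm(12, sd = 2)
  fit <- fit_spline(y, canonical_grid, canonical_knots)
  ll <- spline_loglik(fit, y, canonical_grid)
  expect_equal(ll, fit$loglik, tolerance = 1e-10)
  # density-sum oracle at the MLE variance
  res <- y - evaluate_spline(fit, canonical_grid)
  s2 <- sum(res^2) / 12
  expect_equal(ll, sum(dnorm(res, 0, sqrt(s2), log = TRUE)), tolerance = 1e-10)
  # doubling residuals lowers the log-likelihood
  y2 <- evaluate_spline(fit, canonical_grid) + 2 * res
  expect_lt(spline_loglik(fit, y2, canonical_grid), ll)
})

test_that("spline fit collections serialize and re-validate", {
  set.seed(56)
  tab <- make_raw_table(matrix(exp(rnorm(4 * 12, sd = 0.4)), 4))
  z <- standardize_per_timepoint(compute_lcr(tab))
  fits <- fit_splines(z)
  path <- withr::local_tempfile(fileext = ".json")
  write_spline_fits(fits, path)
  back <- read_spline_fits(path)
  expect_identical(names(back$fits), names(fits$fits))
  for (g in names(fits$fits)) {
    expect_equal(back$fits[[g]]$beta2, fits$fits[[g]]$beta2, tolerance = 1e-12)
    expect_equal(back$fits[[g]]$loglik, fits$fits[[g]]$loglik, tolerance = 1e-12)
  }
  expect_equal(back$knots$K1, fits$knots$K1)
})
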