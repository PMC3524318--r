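#' Simulation settings for synthetic time-order data
#'
#' The generator emulates the kind of short time-course the method targets:
#' the canonical 12-point sampling grid over 32 hours, saturating
#' ("go up or down, then stay flat") response curves on the LCR scale, pair
#' coupling through the linear ODE \eqn{df_b/dt = k_1 f_a + k_2 f_b} with a
#' moderate positive drive (`k1` in 0.3-1) and mild self-decay (`k2` in
#' -0.3-0), and independent Gaussian observation noise.
#'
#' @param n_genes Number of genes for cascade simulations.
#' @param timepoints Sampling times in hours.
#' @param k1_range,k2_range Ranges the coupling coefficients are drawn from.
#' @param noise_sd Observation noise standard deviation on the LCR scale.
#' @param seed Integer seed; every simulation call is reproducible given it.
#' @return A `dton_sim_spec` list.
#' @export
simulation_spec <- function(n_genes = 12,
                            timepoints = c(0, 1, 2, 4, 6, 8, 12, 16, 20, 24, 28, 32),
                            k1_range = c(0.3, 1),
                            k2_range = c(-0.3, 0),
                            noise_sd = 0.05,
                            seed = 1L) {
  timepoints <- as.numeric(timepoints)
  if (any(diff(timepoints) <= 0)) rlang::abort("timepoints must strictly increase")
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  structure(
    list(
      n_genes = n_genes, timepoints = timepoints,
      k1_range = k1_range, k2_range = k2_range,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "dton_sim_spec"
  )
}

#' Logistic ramp response curve
#'
#' A saturating response on the LCR scale: zero at baseline, rising (or
#' falling, for negative amplitude) around `onset` with the given
#' `steepness`, levelling off at `amplitude`.
#'
#' @param onset Onset time (hours): the ramp's midpoint.
#' @param amplitude Asymptotic LCR change (sign sets direction).
#' @param steepness Logistic rate per hour.
#' @return A vectorized function of time with `f(0) = 0`.
#' @export
logistic_ramp <- function(onset, amplitude = 1, steepness = 0.8) {
  force(onset)
  force(amplitude)
  force(steepness)
  function(t) {
    amplitude * (stats::plogis(steepness * (t - onset)) -
      stats::plogis(steepness * (0 - onset)))
  }
}

# integrate df_b/dt = k1 f_a(t) + k2 f_b(t), f_b(0) = 0, on [0, t_max]
solve_coupled_ode <- function(upstream, k1, k2, t_eval) {
  grid <- sort(unique(c(t_eval, seq(min(t_eval), max(t_eval), length.out = 321))))
  sol <- deSolve::ode(
    y = c(fb = 0), times = grid,
    func = function(t, y, parms) list(k1 * upstream(t) + k2 * y[1]),
    rtol = 1e-10, atol = 1e-12
  )
  fb <- sol[match(t_eval, sol[, "time"]), "fb"]
  if (any(!is.finite(fb)) || max(abs(fb)) > 1e6) {
    rlang::abort("ODE solution overflowed; use a smaller |k2| or amplitude")
  }
  fb
}

#' Simulate one coupled gene pair with known time order
#'
#' Gene a follows the `upstream` curve; gene b's rate of change is driven by
#' gene a through \eqn{df_b/dt = k_1 f_a + k_2 f_b} with `f_b(0) = 0`, so b
#' responds strictly after a: the ground-truth order is `a -> b`.
#' Observations are the curves sampled on the grid in `spec` plus independent
#' Gaussian noise.
#'
#' @param k1 Coupling strength from a to b; must be nonzero.
#' @param k2 Self-feedback of b (negative values decay).
#' @param upstream Function of time for gene a's LCR curve (e.g.
#'   [logistic_ramp()]); must vanish at the first time point.
#' @param spec A `dton_sim_spec`; `timepoints`, `noise_sd` and `seed` are used.
#' @param standardize If `TRUE` (default) each noise-free curve is scaled to
#'   unit standard deviation across the sampling grid before noise is added,
#'   emulating observations on the standardized-LCR scale; the linear ODE
#'   family is closed under this per-gene rescaling (it only rescales the
#'   coupling), and the log-likelihood comparison of two different responses
#'   presumes comparable response scales. `FALSE` returns the raw solution.
#' @return A list: `ya`, `yb` (noisy observations), `fa`, `fb` (noise-free
#'   curve values as observed, i.e. after any scaling), `times`, and
#'   `truth = "a->b"`.
#' @export
simulate_pair <- function(k1, k2, upstream = logistic_ramp(6),
                          spec = simulation_spec(), standardize = TRUE) {
  if (k1 == 0) rlang::abort("k1 must be nonzero: no coupling means no time order")
  times <- spec$timepoints
  fa <- upstream(times)
  fb <- solve_coupled_ode(upstream, k1, k2, times)
  if (standardize) {
    fa <- fa / stats::sd(fa)
    fb <- fb / stats::sd(fb)
  }
  withr::with_seed(spec$seed, {
    ya <- fa + stats::rnorm(length(times), sd = spec$noise_sd)
    yb <- fb + stats::rnorm(length(times), sd = spec$noise_sd)
  })
  list(ya = ya, yb = yb, fa = fa, fb = fb, times = times, truth = "a->b")
}

#' Simulate a gene cascade with known onset order
#'
#' Each gene carries its own saturating ramp with a prescribed onset lag;
#' coupled genes are additionally driven by an upstream gene through the
#' pair ODE, so the cascade has a known time order: larger lag means a
#' later response. The noise-free curves are emitted directly on the
#' standardized-LCR scale (unit standard deviation across the grid per
#' gene), emulating genes drawn from a large cohort whose LCRs were
#' standardized genome-wide; a small simulated gene set is not
#' re-standardized against itself. The integrated drive is normalized to
#' unit peak before mixing, so couplings never compound without bound along
#' deep cascades (expression saturates).
#'
#' @param lags Onset lags in hours, one per gene, in cascade order.
#' @param spec A `dton_sim_spec`.
#' @param couple Either `"chain"` (gene i driven by gene i-1), `"none"`
#'   (independent ramps), or an integer vector giving, for each gene, the
#'   index of its upstream driver (0 = none; drivers must precede their
#'   targets).
#' @param amplitudes Optional ramp amplitudes (default: unit magnitude with
#'   seeded random signs).
#' @param ramp_weight Mixing weight of a coupled gene's own ramp versus its
#'   normalized upstream drive (default 0.5: equal parts).
#' @param waves Optional character labels per gene (e.g. early/late);
#'   defaults to `"late"` for lags past the midpoint of the window.
#' @return A list: `table` (a standardized_lcr `dton_expr`), `truth` (tibble
#'   `gene, onset, wave`), and `order` (genes sorted by onset).
#' @export
simulate_cascade <- function(lags, spec = simulation_spec(), couple = "chain",
                             amplitudes = NULL, ramp_weight = 0.5,
                             waves = NULL) {
  n <- length(lags)
  if (n < 2) rlang::abort("a cascade needs at least 2 genes")
  if (anyDuplicated(lags)) {
    rlang::warn("duplicate onset lags: tied genes have no defined mutual order")
  }
  times <- spec$timepoints
  genes <- sprintf("G%02d", seq_len(n))
  if (identical(couple, "chain")) {
    driver <- c(0L, seq_len(n - 1))
  } else if (identical(couple, "none")) {
    driver <- rep(0L, n)
  } else {
    driver <- as.integer(couple)
    stopifnot(length(driver) == n, all(driver < seq_len(n)))
  }
  withr::with_seed(spec$seed, {
    if (is.null(amplitudes)) {
      amplitudes <- sample(c(-1, 1), n, replace = TRUE)
    }
    k1s <- stats::runif(n, spec$k1_range[1], spec$k1_range[2])
    k2s <- stats::runif(n, spec$k2_range[1], spec$k2_range[2])
    curves <- vector("list", n)
    for (i in seq_len(n)) {
      ramp <- logistic_ramp(lags[i], amplitude = amplitudes[i])
      if (driver[i] == 0) {
        curve <- ramp(times)
      } else {
        upstream_fun <- stats::approxfun(times, curves[[driver[i]]], rule = 2)
        drive <- solve_coupled_ode(upstream_fun, k1s[i], k2s[i], times)
        drive <- drive / max(abs(drive))
        # orient the drive with the gene's own response direction
        if (sign(drive[length(drive)]) != sign(amplitudes[i])) drive <- -drive
        curve <- ramp_weight * ramp(times) +
          (1 - ramp_weight) * abs(amplitudes[i]) * drive
      }
      curves[[i]] <- curve / stats::sd(curve) # standardized-LCR scale
    }
    m <- do.call(rbind, curves)
    m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd), nrow = n)
  })
  m[, 1] <- 0 # observations are LCRs: zero at baseline by construction
  colnames(m) <- as.character(times)
  tab <- as_expr_table(
    dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m)),
    stage = "lcr"
  )
  attr(tab, "stage") <- "standardized_lcr"
  if (is.null(waves)) {
    waves <- ifelse(lags > (min(times) + max(times)) / 2, "late", "early")
  }
  truth <- tibble::tibble(gene = genes, onset = lags, wave = waves)
  list(table = tab, truth = truth, order = genes[order(lags)])
}

#' Two-wave cascade lags and couplings
#'
#' Convenience constructor for the benchmark layout: an early wave of
#' independent-onset genes and a late wave in which every gene is driven by
#' a randomly chosen early-wave gene.
#'
#' @param n_early,n_late Genes per wave.
#' @param early_window,late_window Onset-lag ranges (hours).
#' @param seed Integer seed for the lag and coupling draws.
#' @return A list with `lags`, `couple` (driver indices) and `waves`,
#'   ready to pass to [simulate_cascade()].
#' @export
two_wave_design <- function(n_early = 5, n_late = 7,
                            early_window = c(0, 6), late_window = c(18, 26),
                            seed = 1L) {
  withr::with_seed(as.integer(seed), {
    lags <- c(
      stats::runif(n_early, early_window[1], early_window[2]),
      stats::runif(n_late, late_window[1], late_window[2])
    )
    couple <- c(rep(0L, n_early), sample(n_early, n_late, replace = TRUE))
  })
  list(
    lags = lags, couple = couple,
    waves = rep(c("early", "late"), c(n_early, n_late))
  )
}

#' Convert an LCR-scale table to synthetic raw intensities
#'
#' Inverts the LCR transform around a baseline intensity, for exercising the
#' full preprocessing path on simulated data: `C_t = baseline * exp(lcr)`.
#'
#' @param table An lcr- or standardized_lcr-stage `dton_expr`.
#' @param baseline Baseline intensity `C_0` (recycled across genes).
#' @return A raw-stage `dton_expr`.
#' @export
to_raw_intensity <- function(table, baseline = 1000) {
  assert_expr(table, c("lcr", "standardized_lcr"))
  m <- expr_matrix(table)
  raw <- baseline * exp(m)
  out <- dplyr::bind_cols(
    tibble::tibble(gene = table$gene),
    tibble::as_tibble(raw)
  )
  as_expr_table(out, stage = "raw")
}

#' t-test screen for late response genes (baseline comparator)
#'
#' A simple two-filter screen: (i) keep genes whose LCRs over the early
#' window do not deviate significantly from zero, then (ii) among those,
#' keep genes whose late-window LCRs do. Unusually, the thresholds are
#' quantiles of the empirical p-value distributions across genes — the 60th
#' percentile of early p-values and the 5th percentile of late p-values —
#' rather than fixed significance levels, so the screen adapts to the
#' cohort. Both one-sample t-tests are computed per gene.
#'
#' @param table An lcr- or standardized_lcr-stage `dton_expr`.
#' @param early_times,late_times Time subsets defining the two windows.
#' @param early_p_quantile Keep genes with early p-value above this quantile
#'   of the early p-value distribution.
#' @param late_p_quantile Keep genes with late p-value below this quantile
#'   of the late p-value distribution.
#' @return A tibble of selected genes: `gene, p_early, p_late, late_mean,
#'   trend` with trend from the sign of the late-window mean.
#' @export
ttest_late_response_screen <- function(table,
                                       early_times = c(0, 1, 2, 4, 6, 8, 12, 16),
                                       late_times = c(20, 24, 28, 32),
                                       early_p_quantile = 0.6,
                                       late_p_quantile = 0.05) {
  assert_expr(table, c("lcr", "standardized_lcr"))
  times <- expr_times(table)
  if (!all(early_times %in% times) || !all(late_times %in% times)) {
    rlang::abort("early/late windows must be subsets of the table's times")
  }
  if (length(early_times) < 2 || length(late_times) < 2) {
    rlang::abort("each window needs at least 2 time points")
  }
  m <- expr_matrix(table)
  e <- m[, as.character(early_times), drop = FALSE]
  l <- m[, as.character(late_times), drop = FALSE]
  pval <- function(x) {
    if (stats::sd(x) == 0) {
      return(if (mean(x) == 0) 1 else 0)
    }
    stats::t.test(x, mu = 0)$p.value
  }
  p_early <- apply(e, 1, pval)
  p_late <- apply(l, 1, pval)
  cut_early <- unname(stats::quantile(p_early, early_p_quantile, type = 7))
  cut_late <- unname(stats::quantile(p_late, late_p_quantile, type = 7))
  tibble::tibble(
    gene = table$gene,
    p_early = unname(p_early), p_late = unname(p_late),
    late_mean = unname(rowMeans(l))
  ) |>
    dplyr::filter(.data$p_early > cut_early, .data$p_late < cut_late) |>
    dplyr::mutate(
      trend = ifelse(.data$late_mean > 0, "overexpressed", "underexpressed")
    )
}

#' Fraction of true orderings recovered
#'
#' Given pair scores and the ground-truth cascade order, counts the ordered
#' pairs `(a before b)` whose score `delta(a -> b)` is positive.
#'
#' @param scores A `dton_pair_scores` tibble.
#' @param truth A tibble with `gene` and `onset` (as from
#'   [simulate_cascade()]), or a two-column data frame of true ordered pairs
#'   (`from`, `to`).
#' @param adjacent_only With cascade truth, score only consecutive genes in
#'   onset order (default) rather than all ordered pairs.
#' @return The recovery rate in `[0, 1]`.
#' @export
evaluate_direction_recovery <- function(scores, truth, adjacent_only = TRUE) {
  if (all(c("gene", "onset") %in% names(truth))) {
    ord <- truth$gene[order(truth$onset)]
    if (adjacent_only) {
      pairs <- tibble::tibble(
        from = ord[-length(ord)],
        to = ord[-1]
      )
    } else {
      idx <- utils::combn(seq_along(ord), 2)
      pairs <- tibble::tibble(from = ord[idx[1, ]], to = ord[idx[2, ]])
    }
  } else {
    stopifnot(all(c("from", "to") %in% names(truth)))
    pairs <- truth
  }
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$from[i]
    b <- pairs$to[i]
    row <- scores[
      (scores$gene_a == a & scores$gene_b == b) |
        (scores$gene_a == b & scores$gene_b == a), ,
      drop = FALSE
    ]
    if (nrow(row) != 1) rlang::abort(sprintf("no score for pair (%s, %s)", a, b))
    d <- if (row$gene_a == a) row$delta else -row$delta
    d > 0
  }, logical(1))
  mean(hit)
}
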