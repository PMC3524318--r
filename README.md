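# dtonet

Dynamic time order networks for short time-course gene expression data.

## What it does, and for whom

After a stimulus — the motivating setting is 17β-estradiol (E2) treatment
of breast cancer cells sampled 12 times over 32 hours — some genes respond
within the first hours and others only near the end of the course. Late
responders are attractive pharmacodynamic biomarker candidates because
their change persists, but neither clustering nor per-gene testing orders
responses in time. dtonet is for analysts of such time courses: it infers,
for every pair of genes, *which one responds later*, and assembles the
answers into a directed **dynamic time order network** whose incoming-edge
hubs are the late response genes.

## The method

Each gene's standardized log concentration ratio trajectory
(LCR, $y_t = \log C_t/C_0$, z-scored within each time point) is fitted
with a three-piece natural cubic spline with knots at the 33rd/67th
percentiles of the sampling times (5.333 h and 17.333 h on the canonical
grid). Continuity and natural boundary constraints leave 4 free
parameters of the 12 raw cubic coefficients, so the fit is ordinary least
squares on a reduced $12 \times 4$ design matrix.

Time order rests on a coupling ODE: if gene $b$ follows gene $a$,
$$\frac{df_b}{dt} = k_1 f_a(t) + k_2 f_b(t)
\quad\Longleftrightarrow\quad
f_b(t) = k_1 F_a(t) + k_2 F_b(t),$$
with $F_i$ the cumulative (integrated) fitted curves, available in closed
form. For each pair, two regressions share the predictors
$(1, F_a, F_b)$: response $y_b$ scores $a \to b$, response $y_a$ scores
$b \to a$. The difference of their maximized Gaussian log-likelihoods,
$\Delta LL$, is the ordering evidence; its sign gives the edge direction
and $|\Delta LL|$ the edge weight. Small networks are pruned by a
weight-quantile threshold plus transitive reduction; genome-scale networks
by a maximum-weight spanning tree (Prim). Late response genes are reported
as incoming-edge hubs, each labelled over-/under-expressed by the sign of
its mean fitted LCR after the late knot.

A simulator (`simulate_pair()`, `simulate_cascade()`,
`two_wave_design()`) generates ODE-coupled cascades with known time order
for benchmarking, and `ttest_late_response_screen()` provides the
conventional t-test baseline for comparison.

## Worked example

```r
library(dtonet)

# 12-gene benchmark: 5 early ramps, 7 late genes each ODE-driven by an
# early gene; observations on the standardized-LCR scale, noise sd 0.05
d   <- two_wave_design(n_early = 5, n_late = 7, seed = 4)
sim <- simulate_cascade(d$lags, simulation_spec(noise_sd = 0.05, seed = 4),
                        couple = d$couple, waves = d$waves)

res <- run_pipeline(sim$table, dton_config(mode = "mwst", seed = 4))
res$pruned
#> # Time-order network (mwst): 12 genes, 11 directed edges
res$hubs
#> # A tibble: 7 × 5
#>   gene  in_degree out_degree trend          late_mean
#>   <chr>     <int>      <int> <chr>              <dbl>
#> 1 G09           5          0 underexpressed     -1.85
#> 2 G06           1          0 overexpressed       2.22
#> 3 G07           1          0 underexpressed     -2.05
#> ...
```

The spanning tree of the 66 pair scores has 11 edges; seven genes carry
only incoming edges, and the top hub (G09, 5 incoming edges, classified
under-expressed from its fitted late-window mean of −1.85) is exactly the
gene with the latest simulated onset:

```r
sim$truth[order(-sim$truth$onset), ][1:3, ]
#>   gene  onset wave
#> 1 G09    25.6 late
#> 2 G08    25.2 late
#> 3 G11    24.0 late
```

Individual stages are available as plain functions
(`compute_lcr()`, `fit_splines()`, `score_all_pairs()`,
`maximum_weight_spanning_tree()`, ...), results tidy into tibbles via
`tidy()`/`glance()`, and `autoplot()` draws trajectories, spline fits,
score distributions and networks. A thin command-line wrapper lives at
`inst/cli/dton.R`.

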