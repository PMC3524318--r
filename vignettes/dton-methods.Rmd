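---
title: "Dynamic time order networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic time order networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dtonet)
```

## The problem

Short time-course expression experiments — a dozen arrays over a day or two
after a stimulus such as 17β-estradiol (E2) in breast cancer cells — hold
information that steady-state contrasts throw away: *when* each gene
responds. Genes that respond late are attractive pharmacodynamic biomarker
candidates because their change persists; genes that respond early may say
little about the sustained effect of a treatment. Clustering and per-gene
testing do not order responses in time. dtonet builds a *dynamic time order
network* (DTON): a directed graph in which an edge $u \to v$ asserts that
gene $v$ responds later than gene $u$, with an edge weight measuring the
strength of that ordering evidence. Late response genes then surface as
*incoming-edge hubs* — nodes with many incoming edges and none outgoing.

## The model

### Input scale

The raw input is a genes × times intensity table. Preprocessing mirrors
standard time-course practice:

1. duplicate probes are averaged into genes;
2. genes whose coefficient of variation across time (sd/mean, intensity
   scale) is at or below 0.15 are dropped as non-responsive;
3. each gene is converted to log concentration ratios (LCR)
   $y_t = \log(C_t / C_0)$ against the first time point;
4. LCRs are standardized (z-scored) within each time point across genes.

Step 4 makes genes' responses scale-comparable, which matters later: the
pairwise test compares likelihoods of regressions with *different response
variables*, a comparison that is only meaningful when the responses live on
a common scale. The log base in step 3 is immaterial — a base change is a
global positive rescaling absorbed by the z-score — so natural logs are
used; the test suite verifies the invariance. Columns with zero spread
(notably the baseline column, identically zero by construction) are left
unchanged: a z-score is undefined there and zero is the semantically
correct LCR at $t = 0$.

### Trajectory fitting: constrained natural cubic splines

Each gene's standardized LCR trajectory $y_{t}$ is fitted with a
three-piece cubic polynomial $f(t)$ on $[t_{\min}, t_{\max}]$ with knots
$K_1 < K_2$ placed at the 33rd and 67th percentiles of the sampling times
themselves (linear-interpolation quantiles, $h = 1 + (n-1)p$; R's type 7).
On the canonical grid $\{0,1,2,4,6,8,12,16,20,24,28,32\}$ hours this puts
the knots at $16/3 \approx 5.333$ h and $52/3 \approx 17.333$ h, so each
piece covers about a third of the sampling effort, and "late response"
acquires a concrete meaning: change after the second knot.

The three cubics carry 12 raw coefficients, tied by 8 linear constraints:
value, slope and curvature continuity at each knot, and zero curvature at
both window ends (the *natural* boundary conditions). The constraint system
has rank 8, leaving exactly **4 free parameters**; the middle piece's
coefficients $\beta_2 = (\beta_{20}, \beta_{21}, \beta_{22}, \beta_{23})$
are a convenient free set, and the outer pieces follow from two small
linear solves (`solve_outer_coefficients()`). Because the whole constrained
spline is then *linear* in $\beta_2$, fitting reduces to ordinary least
squares on a reduced $n \times 4$ design matrix $T^*$ whose middle-region
rows are exactly $(1, t, t^2, t^3)$:

```{r}
grid <- c(0, 1, 2, 4, 6, 8, 12, 16, 20, 24, 28, 32)
k <- compute_knots(grid)
k
dim(build_design_matrix(grid, k))
```

The test suite confirms the OLS solution coincides (to $10^{-6}$) with a
direct numerical maximization of the 12-parameter Gaussian likelihood under
the 8 equality constraints.

Piece membership uses half-open intervals ($t = K_1$ belongs to the middle
piece, $t = K_2$ to the last); continuity makes the choice value-irrelevant
but it is fixed for bookkeeping. The residual variance estimate is the
Gaussian MLE $\hat\sigma^2 = \mathrm{RSS}/n$, *not* $\mathrm{RSS}/(n-4)$:
the pairwise test below compares maximized log-likelihoods of
equal-complexity models, and both sides must use the same convention.

### Time order by integrated-ODE regression

If gene $b$ responds after gene $a$, a minimal coupling model says $b$'s
rate of change tracks $a$'s level plus self-feedback:
$$\frac{df_b}{dt} = k_1 f_a(t) + k_2 f_b(t).$$
Integrating once replaces rates — noisy to estimate — with cumulative
curves:
$$f_b(t) = k_1 F_a(t) + k_2 F_b(t), \qquad
  F_i(t) = \int_{t_{\min}}^{t} f_i(s)\, ds,$$
which uses the entire trajectory rather than only the early window where
rates differ. The fitted splines integrate in closed form piece by piece
(quartic antiderivatives with continuity constants $C_1 = F(K_1)$,
$C_2 = F(K_2)$; `integrate_spline()`).

For each gene pair the package runs two regressions sharing the predictor
block $X = (1, F_a, F_b)$ evaluated at the observation times:

* response $y_b$: scores the order $a$ before $b$;
* response $y_a$: scores the order $b$ before $a$.

Each is scored by its maximized Gaussian log-likelihood
$-(n/2)(\log 2\pi\hat\sigma^2 + 1)$ with $\hat\sigma^2 = \mathrm{RSS}/n$;
their difference $\Delta LL$ is the ordering evidence, its sign the
inferred direction. $\Delta LL$ is kept as a raw edge weight — no p-value
is attached; edge selection happens in the network step. A numerically
zero RSS is reported as $+\infty$ (perfect fit); two perfect fits tie.
This only arises on noiseless synthetic data.

### Network construction

The scores define a complete directed graph: per pair, one edge in the
positive-$\Delta LL$ direction, weight $|\Delta LL|$; exact ties (a
measure-zero event) contribute no edge. Two simplifications are offered:

* **Small gene sets** (tens of genes): drop edges below a quantile of the
  kept edge-weight distribution (default the median, computed over the
  positive weights only — the zeroed mirror entries are bookkeeping, not
  evidence), then remove transitively implied edges. The length-2 rule —
  drop $A \to C$ when $A \to B$ and $B \to C$ exist — is applied as the
  full transitive reduction (an edge is removed exactly when its target
  remains reachable by a longer path after deleting it), because one-pass
  length-2 removal is order-dependent and non-canonical. On an acyclic
  graph this is the unique minimal reachability-preserving subgraph; edges
  inside directed cycles are never removed and trigger a warning, since
  the rule is ill-defined there.
* **Genome scale**: any single threshold either over-connects or shatters
  the graph, so the network is skeletonized by the maximum-weight spanning
  tree (Prim's algorithm per connected component, hence a forest on
  disconnected inputs). Tree selection ignores direction — $|\Delta LL|$
  measures the strength of the ordering evidence irrespective of its
  orientation — and each selected edge keeps its original direction.
  Weight ties break lexicographically on the node pair, making the result
  deterministic.

Hubs are nodes with in-degree ≥ 1 and out-degree 0, ranked by in-degree
(ties by gene id). Each hub's expression trend is classified by the sign of
its mean fitted LCR over the late window $[K_2, t_{\max}]$, computed
exactly as $(F(t_{\max}) - F(K_2))/(t_{\max} - K_2)$; an exact zero is
reported as under-expressed with an explicit boundary flag.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cv_threshold` | 0.15 | – | drop genes with sd/mean ≤ threshold (strict `>` keeps) |
| `knot_probs` | 1/3, 2/3 | – | sampling-time quantiles for $K_1, K_2$ |
| `quantile` | 0.5 | – | edge-weight quantile cut (small-network mode) |
| `top_hubs` | 10 | genes | hubs reported |
| `noise_sd` | 0.05 | LCR | simulator observation noise |
| `k1_range` | [0.3, 1] | 1/h | simulator coupling strength |
| `k2_range` | [−0.3, 0] | 1/h | simulator self-feedback (decay) |

The defaults reproduce the method's reference settings; `dton_config()`
bundles them and `run_pipeline()` records them in a manifest next to every
output set.

## The synthetic-data generator

No public ZR-75-1 reanalysis ships with the package; the primary test input
is simulated with known ground truth.

* `simulate_pair()` draws one coupled pair from the forward model: an
  upstream saturating logistic ramp (zero at baseline, configurable onset
  and steepness) and a downstream solution of the linear ODE above,
  integrated numerically (deSolve, tolerances $10^{-10}$), observed on the
  canonical grid with i.i.d. Gaussian noise. By default both noise-free
  curves are scaled to unit standard deviation before noise is added,
  emulating observations on the standardized-LCR scale; the ODE family is
  closed under per-gene rescaling (only $k_1$ is rescaled), and the
  likelihood comparison presumes comparable response scales, so this is
  the scale on which the method is meant to operate.
* `simulate_cascade()` builds multi-gene data: each gene has its own ramp
  onset (its lag), and coupled genes add an ODE-integrated drive from an
  upstream gene. Two design choices matter. First, the integrated drive is
  normalized to unit peak before mixing (`ramp_weight`, default half
  ramp / half drive): raw iterated integration compounds like $t^n/n!$ and
  overflows by a dozen genes, whereas real expression saturates. Second,
  curves are emitted directly at unit per-gene standard deviation and the
  table is tagged `standardized_lcr` *without* re-standardizing across the
  simulated genes: genome-wide standardization averages over thousands of
  genes and barely distorts any one trajectory, but z-scoring the columns
  of a 12-gene table would reshape every curve. A small simulated set
  stands for genes drawn from such a standardized cohort.
  `two_wave_design()` generates the benchmark layout: an early wave of
  independent ramps and a late wave in which every gene is driven by a
  random early-wave gene.
* `to_raw_intensity()` inverts the LCR transform around a baseline
  intensity so the full raw-stage preprocessing path can be exercised.

What the generator does *not* emulate: microarray noise structure (dye
bias, saturation, intensity-dependent variance), missing values, stochastic
transcription kinetics, and feedback loops (couplings are strictly
forward). Passing the recovery tests therefore shows the estimator is
correct and robust *under the model and mild misspecification*, not that
it is immune to array artefacts.

A consequence worth knowing: when curves mix a gene's own ramp with
integrated drive (`ramp_weight > 0`), the data are deliberately
misspecified for the pairwise model, and orderings between genes with
*similar* onsets are not reliably recovered even without noise — the
method's strength is separating early from late waves, not resolving
fine-grained order within a wave. With `ramp_weight = 0` (data generated
exactly from the ODE) a noise-free cascade is recovered completely, which
is the self-consistency check in the test suite.

## Numerical choices

* Quantiles (knots, edge thresholds) use the linear-interpolation rule
  $h = 1 + (n-1)p$ throughout.
* OLS is solved by QR; rank deficiency (e.g. collinear cumulative curves)
  raises an informative error rather than a silent pseudo-inverse.
* RSS at or below $10^{-12} \max(1, \sum y^2)$ counts as a perfect fit
  ($+\infty$ log-likelihood, $\hat\sigma^2 = 0$).
* Spline continuity is validated on every constructed fit at $10^{-8}$
  (relative), and serialized fits are re-validated on load.
* The transitive-reduction implementation screens candidate edges with a
  boolean closure (repeated squaring) and confirms each candidate with a
  BFS in the graph minus that edge, so the per-edge definition holds
  exactly even in the presence of cycles elsewhere.

## Problem sizes in the test suite

The suite verifies the constrained-OLS equivalence on 50 random
trajectories, spline continuity on 100, direction recovery on 500 simulated
pairs (noise sd 0.1, ≥ 90% required), Prim against exhaustive spanning-tree
enumeration on 20 random complete graphs (up to 8 nodes, all $n^{n-2}$
trees enumerated via Prüfer sequences), transitive reduction against a
per-edge-deletion oracle on 50 random 10-node DAGs, one 200-gene end-to-end
run (19,900 pairs, 199-edge spanning forest), and a 100-seed top-hub
experiment on 60-gene two-wave cascades (≥ 90% late-wave top hubs
required). These sizes were chosen to exercise each property at meaningful
scale while keeping the default check fast.

## Known limitations

* The two compared regressions have different response variables; their
  likelihood difference is a heuristic ordering score, not a calibrated
  likelihood-ratio test, and no p-value is attached.
* Pairwise scoring is quadratic in the number of genes; the in-memory
  implementation is comfortable to a few thousand genes, which covers the
  intended use. All pair scores are materialized as one tibble.
* Knots are fixed by the sampling design, not adapted to each gene; genes
  whose dynamics concentrate between grid points are smoothed over.
* Orderings within a wave of near-simultaneous genes are weakly
  identified (see above); interpret fine-grained edge directions inside a
  dense wave with caution.
* The MWST highlights incoming-edge hubs (late responders) by
  construction; it is not the right summary for finding *early* response
  genes.
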