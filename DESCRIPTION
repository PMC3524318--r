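Package: dtonet
Title: Dynamic Time Order Networks for Time-Series Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the temporal order of gene responses from short time-course
    expression experiments. Each gene's standardized log-concentration-ratio
    trajectory is fitted with a constrained three-piece natural cubic spline
    (four free parameters), the fitted curves are integrated in closed form,
    and every ordered gene pair is scored by the difference between the
    Gaussian log-likelihoods of the two opposite integrated-ODE regressions.
    The resulting directed, weighted time-order network is simplified either
    by quantile thresholding plus transitive reduction (small gene sets) or by
    a maximum-weight spanning tree (genome scale); incoming-edge hubs identify
    late response genes, candidate pharmacodynamic biomarkers. Includes a
    synthetic cascade simulator with known time order for benchmarking and a
    t-test late-response screen as a baseline comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    deSolve,
    withr,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
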