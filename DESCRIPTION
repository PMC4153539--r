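Package: rncoex
Title: Coexistence by Relative Nonlinearity of Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying coexistence by relative nonlinearity of
    competition in discrete-time population models with non-overlapping
    generations. Implements three classical density-dependence laws
    (Maynard Smith-Slatkin, generalized Ricker, Hassell) with
    density-independent mortality, equilibrium and stability analysis
    including the critical density-compensation strategy at which
    population dynamics become cyclic, adaptive-dynamics invasion analysis
    (pairwise invasibility plots, mutual invasibility, singular-strategy
    detection and classification), and a fast individual-based simulator
    of evolving density-compensation strategies with Poisson reproduction,
    mutation, invasion-probability estimation, competitive-exclusion
    timing, and evolutionary-branching detection under a modified
    growth trade-off.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
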