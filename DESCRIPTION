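Package: invbif
Title: Inverse Bifurcation Analysis of Bistable Mass-Action Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring kinetic parameters of bistable mass-action
    biochemical reaction networks from the measured locations of the
    saddle-node (limit) points of hysteretic dose-response curves. The
    package represents networks through the graph of complexes of Chemical
    Reaction Network Theory, constructs the equilibrium-manifold equations
    and the tangency (multistationarity) condition between the manifold and
    a stoichiometric compatibility class, traces equilibrium branches
    against a conservation constant or a rate constant, and solves the
    resulting inverse-bifurcation optimization problems. Viability sampling
    characterizes identifiable parameter combinations a priori, and a Monte
    Carlo layer propagates replicate measurement noise into percentile
    confidence intervals and parameter correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
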