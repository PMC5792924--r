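Package: isogloss
Title: Surface-Tension Dynamics of Dialect Boundaries on Population Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the spatial spread and extinction of linguistic variants
    as a coarsening process driven by surface tension at dialect boundaries
    (isoglosses). Implements a nonlocal memory-field equation on gridded
    population landscapes with short-range (Gaussian) and long-range
    metropolitan (Lorentzian) interaction kernels, its local reduction,
    closed-form isogloss velocity laws (curvature, population-gradient and
    inherent-bias terms) with stable-radius prediction, a gravity-model
    reduction to coupled city ODEs for hierarchical diffusion, a stochastic
    agent lattice with population mixing and immigration including the
    mean-field extinction threshold, and an ensemble regionalization pipeline
    (randomized initial conditions, Ward clustering, optimal label matching,
    Voronoi null models) that predicts stable dialect areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
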