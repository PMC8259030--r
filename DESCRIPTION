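Package: lactoswitch
Title: Tri-Stable Lactose/pH Genetic Switch Dynamics and Gut Microbiome
    Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic kinetic modelling of a lambda-phage-derived
    tri-stable genetic switch that toggles between beta-galactosidase and
    L-lactate dehydrogenase expression in response to lactose and pH
    signals, coupled to a gut-lumen chemistry model (lactose hydrolysis,
    community fermentation, lactate-dependent pH, enzymatic pH rescue,
    biomass growth) with in-vitro and in-vivo scenario harnesses.
    Companion microbiome time-series toolkit: rarefaction, pseudocounted
    square-root Jensen-Shannon divergence beta diversity, classical
    principal coordinate analysis, Loess PCo1 trajectories with per-day
    Mann-Whitney/Benjamini-Hochberg group tests, and condition-specific
    sparse inverse covariance (graphical lasso) microbial networks with
    StARS stability selection. Includes seeded synthetic-data generators
    (Dirichlet-multinomial count studies, sparse precision-graph Gaussian
    data) so every analysis stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
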