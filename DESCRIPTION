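Package: hmfnet
Title: Multi-Organ Gene Regulatory Network Identification from Expression
    Time Series via Hartley Modulating Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies continuous-time linear ODE models of multi-organ
    gene regulatory networks from short, discretely sampled qPCR expression
    time series. Expression profiles are normalized with a median
    pseudo-reference (-ddCt), imputed, averaged and min-max scaled; the
    Hartley Modulating Function (HMF) method converts the ODE system into a
    frequency-domain linear regression whose coefficients are estimated by
    elastic-net regularization, and candidate models are selected by a
    variance-penalized simulation objective. Downstream analyses cover
    spline-based differential-dynamics testing with a permutation null,
    peak/valley cascade ordering, differential (disease-versus-control)
    network rewiring calls, signed feed-forward-loop motif classification,
    and graph-topology robustness metrics. A synthetic-data generator
    emulates the structure of a two-strain, five-organ qPCR study so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    glmnet,
    deSolve,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
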