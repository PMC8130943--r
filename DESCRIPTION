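Package: sscontrol
Title: Sample-Specific Network Construction and Structural Network Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies per-sample driver genes by combining single-sample
    co-expression network construction (CSN, SSN, paired SSN, SPCC, LIONESS)
    with structural network control (maximum matching, minimum dominating
    set, directed feedback vertex set, and undirected edge-cover control).
    Includes a pinning-control simulator for networked Lorenz oscillators,
    a synthetic-data generator with planted differential edges, and a suite
    of evaluation metrics (F-measure, AUC, Jaccard, controllability,
    hypergeometric enrichment, randomization baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
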