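Package: rnadeg
Title: Structure-Aware Modelling of RNA In-Line Hydrolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and scoring per-nucleotide RNA degradation by
    in-line hydrolysis. Parses dot-bracket secondary structures, assigns
    bpRNA-style loop types, and fits windowed linear (ridge) and gradient-boosted
    models of degradation from one-hot sequence and loop-type context
    ('DegScore'-family models). Aggregates per-nucleotide rates into whole-mRNA
    degradation rates and half-lives, scores predictions with the mean column
    RMSE (MCRMSE) and signal-to-noise metrics used in chemical-mapping work,
    curates datasets by signal-to-noise filtering and cluster-based blind-test
    splits, combines prediction sets by averaging or genetic-algorithm subset
    selection, and generates synthetic benchmark datasets with planted
    sequence-structure degradation signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
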