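Package: topoqsar
Title: Topological Proximity Descriptors and GA-MLR QSAR Modelling for
    Factor Xa Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    models for anti-thrombotic factor Xa inhibitors from SMILES strings.
    Parses molecules into annotated hydrogen-suppressed graphs (aromaticity,
    hybridization, ring membership, Gasteiger-Marsili partial charges,
    all-pairs topological distances), computes atom-class proximity
    descriptors (counts of target atoms at or within a given bond distance
    from source atoms, and partial-charge sums), and couples objective
    feature selection with a genetic-algorithm subset search scored by
    leave-one-out cross-validation over ordinary least squares. Ships the
    published six-descriptor model for factor Xa inhibition and a complete
    validation suite: leave-one-out and leave-many-out Q2, external
    prediction statistics (Q2-F1/F2/F3, concordance correlation,
    through-origin diagnostics), Y-scrambling, and the Williams-plot
    applicability domain. A synthetic-molecule and planted-response
    generator makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
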