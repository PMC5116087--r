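Package: ipanda
Title: Topology- and Statistics-Weighted Pathway Activation Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signed per-sample pathway activation scores for case/control
    transcriptomic data (the iPANDA method): gene-level log fold changes
    against a normal reference are combined with smooth cosine statistical
    weights derived from group t-test P values and topological weights
    derived from walk counts on directed pathway graphs, with coexpressed
    genes collapsed into modules that act as single units. Includes a
    weighted Fisher combined-probability significance test, AUC-based
    pathway marker ranking, the CMP cross-dataset robustness index, and
    seeded synthetic-data generators (pathway databases, module-structured
    coexpression, planted case/control perturbations, dual-platform
    replicates) that exercise the full pipeline without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'differential.R'
    'io.R'
    'ipanda-package.R'
    'markers.R'
    'modules.R'
    'pipeline.R'
    'scoring.R'
    'simulate.R'
    'topology.R'
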