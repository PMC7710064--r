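Package: hierpheno
Title: Ontology-Aware Hierarchical Prediction of Gene Loss-of-Function Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Human Phenotype Ontology (HPO) classes for genes from
    their Gene Ontology (GO) function annotations and tissue expression
    profiles. Provides OBO ontology parsing with true-path-rule annotation
    propagation, a neural multi-label classifier with a hierarchical
    classification layer that enforces ontology consistency during training
    and prediction, naive and GO-to-HPO co-occurrence baselines, CAFA-style
    protein-centric evaluation (Fmax, Smin, AUPR) and term-centric AUROC,
    Resnik/best-match-average semantic similarity with phenotype-based
    gene-disease ranking, a permutation test for interaction-network overlap
    of predictions, and a synthetic-data generator with planted GO-to-HPO
    rules for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
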