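Package: erconcord
Title: Cluster-Based Concordance Evaluation of Reduced Estrogen Receptor
    Assay Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the chemistry domain of applicability of reduced
    (subset) estrogen receptor agonist screening models. Clusters a chemical
    universe by Tanimoto distance over binary structural fingerprints with
    Ward hierarchical clustering, maps assay-tested chemicals into those
    clusters by k-nearest neighbours, recomputes subset-model agonist AUC
    scores from chemical-assay AUC tables and assay weights, compares the
    resulting activity calls against a full-model reference on a per-cluster
    basis, and triages false-positive predictions into screening-relevant
    categories (antagonist overlap, low AUC, low active-assay count). Ships a
    synthetic-data generator with planted cluster structure and activity
    archetypes so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
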