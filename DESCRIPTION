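Package: topoQSPR
Title: Degree-Based Topological Indices and QSPR Modeling of Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes nine degree-based topological indices (atom-bond
    connectivity, Randic, sum-connectivity, geometric-arithmetic, first and
    second Zagreb, harmonic, hyper-Zagreb and forgotten indices) of
    hydrogen-suppressed molecular graphs via endpoint-degree edge partitions,
    and fits univariate linear quantitative structure-property relationship
    (QSPR) models of physicochemical properties on those indices. Bundles the
    descriptor and property tables for eleven vitiligo-treatment drugs together
    with a discrepancy ledger, regenerates the published statistical,
    correlation and prediction tables, and includes a seeded generator of
    random chemistry-like graphs with synthetic linear properties for
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
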