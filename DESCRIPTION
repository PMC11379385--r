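Package: mtinegbench
Title: Benchmarking Negative-Data Generation for miRNA-Target Interaction Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate and evaluate negative (non-interacting) examples
    for the classification of miRNA-mRNA target interactions. Implements six
    negative-generation strategies (mock miRNA, three mock-mRNA variants,
    non-positive-site scanning of CLASH and CLIP data, database-derived
    negatives), a duplex validity scheme based on canonical/non-canonical seed
    pairing and base-pairing density, a 500-feature interaction representation
    with site-accessibility profiles, and an intra-/cross-dataset machine
    learning benchmark with repeated shared-positive splits, one-class
    comparisons, SHAP-based model comparison and miRNA-distribution statistics.
    A seeded synthetic-world generator emulates CLASH/CLIP/TarBase-style inputs
    so the full pipeline runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xgboost,
    e1071,
    ranger,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
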