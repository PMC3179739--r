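Package: scaffdiv
Title: Scaffold and Fingerprint Diversity Analysis of Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative diversity analysis of small-molecule compound
    collections. Reads and standardizes SMILES/SDF libraries, reduces
    redundancy by CLARA-style k-medoids clustering on atom-type count
    descriptors, generates extended-connectivity circular fingerprints
    (connectivity and functional-class variants), computes binary and
    frequency-weighted Tanimoto similarity between whole datasets,
    profiles Lipinski rule-of-five and extended physicochemical
    descriptors, and performs Bemis-Murcko scaffold analytics
    (singletons, aromatic fractions, top scaffolds, shared-scaffold
    matrices, missing-scaffold reports). Includes a synthetic library
    generator with per-molecule ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
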