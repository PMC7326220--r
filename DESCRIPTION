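Package: ssptools
Title: Evaluation and Target-Dataset Reduction Toolkit for Protein
    Secondary Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the evaluation and acceleration of protein secondary
    structure prediction (SSP) pipelines that build PSI-BLAST
    position-specific scoring matrices (PSSMs) against large target
    datasets. Provides rigorous accuracy measures (micro-average Q3/Q8 and
    size-weighted segment-overlap SOV3/SOV8), Shannon information entropy
    of PSSM profiles as a profile-quality measure, construction of size-
    and homology-reduced non-redundant sequence datasets by seeded random
    sampling and a divide-and-conquer greedy clustering algorithm, and
    fitted speed/accuracy performance models relating target-dataset size
    and identity cutoff to prediction time cost and accuracy. Synthetic
    generators for sequence families, secondary-structure string pairs and
    PSSM profiles make every component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
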