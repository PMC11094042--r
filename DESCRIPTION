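Package: missbench
Title: Benchmarking Residue-Level Missense Pathogenicity Scores Against Clinical Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating residue-level missense pathogenicity
    predictions (AlphaMissense-style score tables) against clinically
    labelled variants. Implements three-class score thresholding with an
    ambiguous band, confusion-table construction under two ambiguity
    policies, PPV/TPR/F1/MCC and rank-based aucROC, protein-set, region
    (e.g. transmembrane) and pLDDT-confidence restricted benchmarking with
    length-normalised mutation frequencies, single-nucleotide-variant
    reachability from the standard genetic code, 20x20 ordered substitution
    score matrices with asymmetry and BLOSUM62 correlation analysis,
    per-residue mean-score profiles written into PDB occupancy/B-factor
    columns, and a seeded synthetic cohort generator so every pipeline
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    bio3d,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
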