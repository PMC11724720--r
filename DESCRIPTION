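Package: pcmscreen
Title: Proteochemometric Screening of Nuclear Receptor Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteochemometric (PCM) modeling for predicting small-molecule
    binders of nuclear receptors. Builds a 217-dimensional pair descriptor
    from a 30-member reference panel of receptor sequences (normalized
    Smith-Waterman similarities) and 187 two-dimensional physicochemical and
    topological ligand descriptors, trains a random-forest classifier with
    class-balancing oversampling and Gaussian feature noise, and reports
    tri-level activity calls. Includes the evaluation protocol (ROC-AUC,
    best-balanced-accuracy cutoff selection, train-fraction by oversampling
    grids, protein/ligand descriptor ablations), matched-molecular-pair
    scaffold mining with chemical-space networks, and a deterministic
    synthetic-data generator with a planted protein-ligand interaction rule
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
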