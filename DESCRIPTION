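Package: immunopep
Title: Sequence-Based Prediction of T-Cell Epitope and Neoantigen
    Immunogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the T-cell immunogenicity of HLA class-I presented
    peptides (8-12 residues) and single-substitution neoantigens from
    sequence-derived features.  Computes physicochemical scale averages,
    a class-conditional contact-site frequency score and a background
    peptide entropy over the TCR-contact positions of each peptide
    (anchor positions excluded), combines them with a supplied
    MHC-binding percentile rank, screens features against permuted shadow
    probes, and trains a random-forest classifier with repeated
    stratified cross-validation.  Includes curation filters for building
    training sets (binding-rank and human-proteome filters for the
    negative class, HLA supertype mapping), neoantigen mutation features
    (hydrophobicity change, differential agretopicity index,
    anchor-mutation flag), a synthetic-data generator emulating
    supertype anchor motifs and class-dependent contact-site
    composition, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
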