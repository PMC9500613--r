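Package: acylsite
Title: Lysine Succinylation and Malonylation Site Quantitation and
    Drug-Attenuation Analysis for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of label-free shotgun-proteomics peptide
    quantitation tables carrying variable lysine acylation (succinylation,
    malonylation). Provides peptide-table, FASTA, GMT and study-design
    readers; mass-error and missed-cleavage filtering with the
    modified-lysine exclusion; Hi-N (top-3) protein quantitation; one-way
    ANOVA differential calling of modified peptides with per-protein
    direction summaries; a threshold-band classifier grading attenuation of
    drug-induced PTM dysregulation after co-treatment; hypergeometric
    over-representation analysis with Benjamini-Hochberg FDR; and a
    synthetic-data generator with planted effects and ground truth for
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
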