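Package: phosvar
Title: Phosphorylation Variability and Structural Context in Cell Cycle
    Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline relating the temporal variability of protein
    phosphorylation across the cell cycle to the structural context of each
    phospho-site. Computes a per-site variability statistic (standard
    deviation of six cell-cycle-phase SILAC ratios), merges secondary
    structure and intrinsic disorder predictions into regular, irregular
    and disordered site categories, compares variability distributions
    across categories, performs two-sample-logo and composition-profile
    statistics on flanking sequence windows, tests enrichment of proximal
    multi-phosphorylation in disordered regions with Fisher's exact test,
    locates kinase recognition motifs in a rank-based two-dimensional
    (variability, disorder) enrichment space, and compares evolutionary
    rates of phospho-sites against matched control residues. Includes a
    calibrated synthetic-data generator so every stage is testable without
    external predictor runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
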