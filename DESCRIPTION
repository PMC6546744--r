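Package: betscreen
Title: Integrative Screen Analysis of BET-Bromodomain Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipeline that nominates mediator genes of
    BET-bromodomain inhibitor (BETi) response in MYC-driven medulloblastoma by
    integrating three evidence layers: transcriptional suppression after drug
    (signal-to-noise marker selection with permutation p-values), CRISPR
    knockout essentiality (an empirical two-component mixture model converting
    gene depletion scores into dependency probabilities), and ORF
    overexpression rescue screens (log-fold-change enrichment with robust-z
    q-values). Auxiliary quantifications include gene-level ChIP-seq binding
    Z-scores, clonal DNA-barcode survival and sharing analysis, gene-set
    overlap statistics, and Bliss-independence drug-synergy scoring. Synthetic
    data generators with planted ground truth make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
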