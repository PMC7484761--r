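Package: glomsig
Title: Glomerular Proteome Signatures and Drug-Repurposing Connectivity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a label-free glomerular proteomics
    drug-repurposing workflow for diabetic kidney disease. Provides seeded
    synthetic-data generators with planted ground truth (study tables with
    MNAR missingness, ortholog maps, compound-signature databases, gene-set
    collections), MaxQuant-style preprocessing (contaminant/peptide filtering,
    median normalization, per-comparison quantification filtering, low-percentile
    noise imputation), per-protein Welch differential abundance with
    Benjamini-Hochberg annotation, the ramipril-insensitive / ramipril-sensitive
    signature-selection flowchart, mouse-to-human signature conversion,
    Kolmogorov-Smirnov connectivity scoring of up/down gene queries against
    compound-instance ranking databases (enrichment, permutation p, specificity,
    percent non-null, and a CMap2-style standardized score), and hypergeometric
    gene-set overlap enrichment with FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
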