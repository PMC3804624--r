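Package: vcmnet
Title: Transcriptomic Staging and Regulatory Network Analysis of
    Ventricular Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for staged expression profiles of purified
    ventricular cardiomyocytes (embryonic-stem-cell derived, fetal and
    adult) against undifferentiated stem cells: sample-level hierarchical
    clustering and principal-component staging with a developmental-axis
    linearity statistic, two-group fold-change screens, abundance-based
    marker discovery with tissue-specificity filtering, gene-set
    enrichment with permutation false-discovery control, co-expression
    network construction over a cardiac transcription-factor panel by
    Pearson-correlation thresholding of four-group mean profiles, and
    information-weighted position-weight-matrix promoter scanning
    integrated into a transcription-factor to target regulatory
    hierarchy. Includes a seeded synthetic-data generator with planted
    gene classes, a planted transcription-factor module and planted
    promoter motif instances for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
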