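Package: transeff
Title: Estimation of Translation Efficiency from Paired mRNA and Protein Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates per-gene translation efficiency (TE) across human cell
    lines from paired transcript abundance (FPKM), protein abundance (iBAQ)
    and pulsed-SILAC protein turnover data, under a steady-state model in
    which TE = iBAQ x PSAT / FPKM with PSAT = 1 - exp(-kdeg), the protein
    stability accounting term. Includes conversion of raw mass-spectrometry
    intensities to iBAQ via predicted tryptic digestion, between-sample
    quantile normalization, cross-cell-line consistency analysis of TE
    (coefficient of variation with a permutation null), quintile and
    quintile-intersection grouping, a local EASE/Fisher annotation-term
    enrichment engine with Benjamini-Hochberg correction, and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
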