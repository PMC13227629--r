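Package: rettomics
Title: Spatiotemporal Multi-Omics Analysis of Rett Syndrome Forebrain Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of the computational procedures used
    to analyse paired transcriptomic and proteomic profiles of Rett-syndrome
    (MECP2-mutant) and isogenic-control forebrain organoids across brain
    regions and differentiation time points: stratified differential
    expression over the seven canonical contrasts with a signed -log10 P
    ranking score, preranked gene set enrichment with permutation-count
    nulls and cross-contrast aggregation, reference-spline pseudotime,
    differential isoform usage, allele-specific expression and imprinting
    statistics, post-transcriptional event detection, and tree-ensemble
    regulator network inference, together with a synthetic-data generator
    that emulates the study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
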