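Package: panelval
Title: Validation Analytics for Targeted Gene-Panel Versus Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for benchmarking a custom targeted gene-panel sequencing
    (TS) assay against whole-exome sequencing (WES) restricted to the panel's
    target regions. Models panel designs (genes, exons, flanked and merged
    target intervals) with exact interval arithmetic and BED I/O; computes
    per-sample and per-gene coverage summaries with paired signed-rank and
    chi-squared comparisons; normalizes, matches and filters annotated
    variant callsets (depth, allele-fraction and target-region filters);
    triages variants into a high-functional-impact class from ClinVar
    significance, population allele frequency and CADD scores; computes
    cross-platform concordance, detection rate and specificity with truth
    assignment from orthogonal confirmation labels and a discrepancy-reason
    taxonomy; and generates fully synthetic panels, depth tracks and paired
    callsets with planted ground truth for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    methods,
    optparse,
    withr
Config/testthat/edition: 3
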