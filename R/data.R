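#' Printed discrepant-variant rows from the validation cohort
#'
#' The nine high-functional-impact variants uniquely detected by one
#' platform in the 19-sample panel-versus-exome validation cohort, with the
#' annotation columns as published: gene, rsID, coding change, consequence,
#' ClinVar significance, CADD score, ExAC non-Finnish-European allele
#' frequency, Sanger confirmation, local GC content, sequencing depth in
#' the detecting and the other platform, and the proposed discrepancy
#' reason. `platform` is the uniquely detecting platform.
#'
#' @return tibble with nine rows
#' @export
discrepant_variant_table <- function() {
  path <- system.file("extdata", "discrepant_variants.tsv",
                      package = "panelval", mustWork = TRUE)
  d <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                                    na.strings = c("NA", "")))
  d$clinvar_sig <- map_clinvar_sig(d$clinvar_raw)
  d
}

#' Per-sample coverage summaries from the validation cohort
#'
#' The published per-sample coverage of the panel target regions in the
#' 19-sample cohort: TS mean depth, percent of target bases at 10x or more
#' in TS, WES mean depth over the same regions, and percent at 10x or more
#' in WES.
#'
#' @return tibble with 19 rows and columns `sample`, `ts_mean_depth`,
#'   `ts_pct_ge10`, `wes_mean_depth`, `wes_pct_ge10`
#' @export
cohort_coverage_table <- function() {
  path <- system.file("extdata", "cohort_coverage.tsv",
                      package = "panelval", mustWork = TRUE)
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Bundled toy panel fixture
#'
#' A six-gene synthetic stand-in for a full diagnostic panel (the real
#' 82-gene list is not bundled), one gene per category, for examples and
#' tests.
#'
#' @return gene-model tibble suitable for [build_targets()]
#' @export
toy_panel <- function() {
  read_gene_models(system.file("extdata", "toy_panel.tsv",
                               package = "panelval", mustWork = TRUE))
}
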