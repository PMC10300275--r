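#' Default thresholds for the high-functional-impact cascade
#'
#' @param maf_rare MAF below which a non-Pathogenic variant is rare enough
#'   to pass on rarity alone (default 0.005, strict `<`)
#' @param maf_max upper MAF bound of the mid-frequency band (default 0.05;
#'   the band is the closed interval `[maf_rare, maf_max]`)
#' @param cadd_min CADD score a mid-frequency variant must exceed
#'   (default 20, strict `>`)
#' @return named list of thresholds
#' @export
hfi_thresholds <- function(maf_rare = 0.005, maf_max = 0.05, cadd_min = 20) {
  stopifnot(maf_rare > 0, maf_max >= maf_rare, cadd_min > 0)
  list(maf_rare = maf_rare, maf_max = maf_max, cadd_min = cadd_min)
}

# default synonym table: regexes on a lower-cased, punctuation-collapsed
# consequence string, checked in order
consequence_synonyms <- function() {
  list(
    exonic_nonsynonymous = paste0(
      "non ?synonymous|missense|stop ?gain|stop ?gained|nonsense|",
      "frameshift|stop ?lost|stop ?loss|start ?lost|start ?loss"),
    splice_site = "splic",
    utr = "\\butr\\b|5 ?prime utr|3 ?prime utr|\\b[53] utr\\b"
  )
}

#' Classify raw consequence annotations into the four-class vocabulary
#'
#' Maps common annotation-tool vocabularies (`missense_variant`,
#' `stopgain`, `frameshift insertion`, `5'UTR`, `splicing`, ...) into
#' `exonic_nonsynonymous`, `utr`, `splice_site` or `other`; `other`
#' covers synonymous, intronic and everything else. Empty or missing
#' strings map to `other` with a warning.
#'
#' @param consequence character vector of raw consequence strings
#' @param synonyms named list of regular expressions tried in order; see
#'   `panelval:::consequence_synonyms()` for the default
#' @return character vector over
#'   `c("exonic_nonsynonymous", "utr", "splice_site", "other")`
#' @export
#' @examples
#' classify_consequence(c("Exonic non-synonymous", "synonymous SNV",
#'                        "splicing"))
classify_consequence <- function(consequence,
                                 synonyms = consequence_synonyms()) {
  key <- tolower(gsub("[^a-z0-9]+", " ", tolower(as.character(consequence))))
  key <- gsub("\\b([53]) (prime )?utr\\b|\\butr *([53])?\\b", " utr ", key)
  out <- rep("other", length(consequence))
  for (cls in rev(names(synonyms))) {
    out[grepl(synonyms[[cls]], key)] <- cls
  }
  # "synonymous" alone must not ride on the non-synonymous pattern
  out[grepl("\\bsynonymous\\b", key) & !grepl("non ?synonymous", key) &
        out == "exonic_nonsynonymous"] <- "other"
  empty <- is.na(consequence) | !nzchar(trimws(as.character(consequence)))
  if (any(empty)) {
    warning("empty consequence string(s) classified as 'other'",
            call. = FALSE)
    out[empty] <- "other"
  }
  out
}

#' High-functional-impact verdicts for annotated variants
#'
#' A variant qualifies as high functional impact (HFI) only if its
#' consequence class is exonic non-synonymous, UTR or splice-site, and then
#' by the first criterion it meets, in order:
#' * `A_clinvar_plp` — ClinVar Pathogenic or Likely pathogenic;
#' * `B_rare_vus` — MAF below `maf_rare` (a missing or zero population
#'   frequency counts as rare);
#' * `C_midfreq_cadd` — MAF in `[maf_rare, maf_max]` and CADD strictly
#'   above `cadd_min` (missing CADD fails).
#'
#' ClinVar Benign / Likely-benign labels do not exclude a variant from
#' criteria B and C: "VUS" is read operationally as "not ClinVar
#' Pathogenic/Likely-pathogenic".
#'
#' @param calls callset tibble (or any tibble with `consequence`,
#'   `clinvar_sig`, `maf_exac_nfe`, `cadd` columns)
#' @param thresholds see [hfi_thresholds()]
#' @return tibble with `consequence_class`, `criterion`
#'   (`A_clinvar_plp`, `B_rare_vus`, `C_midfreq_cadd` or `none`) and
#'   `is_hfi`, one row per input call
#' @export
is_hfi <- function(calls, thresholds = hfi_thresholds()) {
  cls <- classify_consequence(calls$consequence)
  eligible <- cls != "other"
  maf <- ifelse(is.na(calls$maf_exac_nfe), 0, calls$maf_exac_nfe)
  cadd <- calls$cadd
  critA <- calls$clinvar_sig %in% c("Pathogenic", "Likely_pathogenic")
  critB <- maf < thresholds$maf_rare
  critC <- maf >= thresholds$maf_rare & maf <= thresholds$maf_max &
    !is.na(cadd) & cadd > thresholds$cadd_min
  criterion <- rep("none", nrow(calls))
  criterion[eligible & critC] <- "C_midfreq_cadd"
  criterion[eligible & critB] <- "B_rare_vus"
  criterion[eligible & critA] <- "A_clinvar_plp"
  tibble::tibble(consequence_class = cls, criterion = criterion,
                 is_hfi = criterion != "none")
}

#' Partition a callset into HFI and non-HFI calls
#'
#' @inheritParams is_hfi
#' @return list with `hfi` (the qualifying calls), `verdicts` (per-call
#'   verdict tibble, keyed), and `counts` (calls per criterion)
#' @export
classify_callset <- function(calls, thresholds = hfi_thresholds()) {
  v <- is_hfi(calls, thresholds)
  v <- dplyr::bind_cols(tibble::tibble(key = variant_key(calls)), v)
  counts <- table(factor(v$criterion,
                         levels = c("A_clinvar_plp", "B_rare_vus",
                                    "C_midfreq_cadd", "none")))
  list(hfi = calls[v$is_hfi, , drop = FALSE], verdicts = v,
       counts = as.list(counts))
}
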