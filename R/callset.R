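CALLSET_COLUMNS <- c("sample_id", "platform", "chrom", "pos", "ref", "alt",
                     "depth", "alt_fraction", "filter_pass", "rsid",
                     "consequence", "clinvar_sig", "maf_exac_nfe", "cadd",
                     "gene", "gc_pct", "repeat_flag")

CLINVAR_LEVELS <- c("Pathogenic", "Likely_pathogenic", "Uncertain",
                    "Conflicting", "Likely_benign", "Benign", "Not_found")

#' Map ClinVar significance strings onto the package's closed vocabulary
#'
#' Case-insensitive mapping of common ClinVar/annotation-server spellings
#' ("Uncertain significance", "Conflicting interpretations of
#' pathogenicity", "likely benign", ...) onto
#' `Pathogenic, Likely_pathogenic, Uncertain, Conflicting, Likely_benign,
#' Benign, Not_found`. Unrecognized strings map to `Not_found` with a
#' warning; `NA` and empty strings map silently.
#'
#' @param x character vector of raw significance strings
#' @return character vector over the closed seven-value set
#' @export
map_clinvar_sig <- function(x) {
  key <- tolower(gsub("[^a-z]+", " ", tolower(as.character(x))))
  key <- trimws(key)
  out <- rep("Not_found", length(x))
  out[grepl("^pathogenic", key)] <- "Pathogenic"
  out[grepl("likely pathogenic", key)] <- "Likely_pathogenic"
  out[grepl("uncertain|vus", key)] <- "Uncertain"
  out[grepl("conflicting", key)] <- "Conflicting"
  out[grepl("^benign", key) | grepl(" benign$", key) & !grepl("likely", key)] <- "Benign"
  out[key == "benign"] <- "Benign"
  out[grepl("likely benign", key)] <- "Likely_benign"
  known <- out != "Not_found" |
    key %in% c("", "not found", "na", "none", "absent", ".") | is.na(x)
  if (any(!known)) {
    warning("unrecognized ClinVar significance mapped to Not_found: ",
            paste(unique(x[!known]), collapse = ", "), call. = FALSE)
  }
  out
}

validate_callset <- function(calls) {
  miss <- setdiff(CALLSET_COLUMNS, names(calls))
  if (length(miss)) {
    stop("callset missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls) == 0) return(invisible(calls))
  ok_allele <- function(a) grepl("^[ACGT]+$", a)
  bad <- which(!ok_allele(calls$ref) | !ok_allele(calls$alt) |
                 calls$ref == calls$alt | calls$pos < 1)
  if (length(bad)) {
    stop(sprintf("invalid variant record at row %d: %s:%s %s>%s", bad[1],
                 calls$chrom[bad[1]], calls$pos[bad[1]],
                 calls$ref[bad[1]], calls$alt[bad[1]]), call. = FALSE)
  }
  maf <- calls$maf_exac_nfe
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("maf_exac_nfe outside [0,1]", call. = FALSE)
  }
  af <- calls$alt_fraction
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("alt_fraction outside [0,1]", call. = FALSE)
  }
  if (!all(calls$platform %in% c("TS", "WES"))) {
    stop("platform must be TS or WES", call. = FALSE)
  }
  invisible(calls)
}

#' Read and write annotated callsets in the flat TSV dialect
#'
#' Tab-separated with header columns `sample_id, platform, chrom, pos, ref,
#' alt, depth, alt_fraction, filter_pass, rsid, consequence, clinvar_sig,
#' maf_exac_nfe, cadd, gene, gc_pct, repeat_flag` (`pos` 1-based, VCF
#' convention). Missing optional fields may be empty. A write-then-read
#' round trip is lossless for these fields.
#'
#' @param path file path
#' @param platform if given, overrides/sets the platform column and errors
#'   on a mismatch with the file contents
#' @return callset tibble
#' @export
read_callset <- function(path, platform = NULL) {
  # ref/alt like "T" must never be sniffed as logicals
  classes <- c(sample_id = "character", platform = "character",
               chrom = "character", ref = "character", alt = "character",
               rsid = "character", consequence = "character",
               clinvar_sig = "character", gene = "character",
               filter_pass = "character", repeat_flag = "character")
  d <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                                    na.strings = c("NA", ""),
                                    colClasses = classes))
  if (!is.null(platform)) {
    if (!platform %in% c("TS", "WES")) stop("unknown platform: ", platform,
                                            call. = FALSE)
    if ("platform" %in% names(d) &&
        any(!is.na(d$platform) & d$platform != platform)) {
      stop("file platform column disagrees with platform = ", platform,
           call. = FALSE)
    }
    d$platform <- platform
  }
  d$chrom <- as.character(d$chrom)
  d$ref <- toupper(as.character(d$ref))
  d$alt <- toupper(as.character(d$alt))
  if (is.character(d$filter_pass)) {
    d$filter_pass <- toupper(d$filter_pass) %in% c("TRUE", "PASS", "1", "YES")
  }
  if (is.character(d$repeat_flag)) {
    d$repeat_flag <- toupper(d$repeat_flag) %in% c("TRUE", "1", "YES")
  }
  d$clinvar_sig <- map_clinvar_sig(d$clinvar_sig)
  validate_callset(d)
  d[, CALLSET_COLUMNS]
}

#' @param calls callset tibble
#' @rdname read_callset
#' @export
write_callset <- function(calls, path) {
  validate_callset(calls)
  write.table(calls[, CALLSET_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an annotated callset from a VCF file
#'
#' Thin wrapper over `VariantAnnotation::readVcf()`. Multi-allelic records
#' are split into one row per alternate allele before any matching. INFO
#' keys holding the annotations are configurable; per-sample depth and
#' allele fraction are taken from the `DP` and `AD`/`AF` FORMAT fields when
#' present, else from INFO `DP`.
#'
#' @param path path to an (uncompressed or bgzipped) VCF 4.x file
#' @param platform `"TS"` or `"WES"`
#' @param sample_id sample identifier; defaults to the first VCF sample
#'   name, or `"sample1"` for site-only files
#' @param info_keys named list mapping the annotation fields to INFO keys:
#'   `clinvar` (default `"CLNSIG"`), `cadd` (`"CADD"`), `maf`
#'   (`"ExAC_NFE"`), `consequence` (`"CSQ"`), `gene` (`"GENE"`)
#' @return callset tibble in the flat dialect
#' @export
read_callset_vcf <- function(path, platform = c("TS", "WES"),
                             sample_id = NULL,
                             info_keys = list()) {
  platform <- match.arg(platform)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_callset_vcf requires the VariantAnnotation package",
         call. = FALSE)
  }
  keys <- utils::modifyList(
    list(clinvar = "CLNSIG", cadd = "CADD", maf = "ExAC_NFE",
         consequence = "CSQ", gene = "GENE"), info_keys)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  if (n == 0) {
    return(tibble::as_tibble(setNames(
      rep(list(character(0)), length(CALLSET_COLUMNS)), CALLSET_COLUMNS)))
  }
  get_info <- function(key, default = NA) {
    if (!is.null(key) && key %in% names(info)) {
      v <- info[[key]]
      if (methods::is(v, "List")) {
        v <- vapply(v, function(e) if (length(e)) paste(e, collapse = ","
                                                        ) else NA_character_, "")
      }
      v
    } else rep(default, n)
  }
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(n), n_alt)
  if (is.null(sample_id)) {
    sn <- colnames(vcf)
    sample_id <- if (length(sn)) sn[1] else "sample1"
  }
  depth <- rep(NA_integer_, n)
  afrac <- rep(NA_real_, n)
  gt <- VariantAnnotation::geno(vcf)
  if ("DP" %in% names(gt)) depth <- as.integer(gt$DP[, 1])
  else if ("DP" %in% names(info)) depth <- as.integer(info$DP)
  if ("AF" %in% names(gt)) {
    afrac <- as.numeric(vapply(gt$AF[, 1], `[`, 0, 1))
  } else if ("AD" %in% names(gt)) {
    ad <- gt$AD[, 1]
    afrac <- vapply(ad, function(a)
      if (length(a) >= 2 && sum(a) > 0) a[2] / sum(a) else NA_real_, 0)
  }
  filt <- as.character(VariantAnnotation::filt(vcf))
  rsid <- names(rr)
  if (is.null(rsid)) rsid <- rep(NA_character_, n)
  rsid[!grepl("^rs", rsid)] <- NA_character_
  out <- tibble::tibble(
    sample_id = sample_id,
    platform = platform,
    chrom = as.character(GenomeInfoDb::seqnames(rr))[idx],
    pos = BiocGenerics::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(alts)),
    depth = depth[idx],
    alt_fraction = afrac[idx],
    filter_pass = (filt %in% c("PASS", "."))[idx],
    rsid = rsid[idx],
    consequence = as.character(get_info(keys$consequence, NA_character_))[idx],
    clinvar_sig = map_clinvar_sig(get_info(keys$clinvar, NA_character_))[idx],
    maf_exac_nfe = as.numeric(get_info(keys$maf, NA_real_))[idx],
    cadd = as.numeric(get_info(keys$cadd, NA_real_))[idx],
    gene = as.character(get_info(keys$gene, NA_character_))[idx],
    gc_pct = NA_real_,
    repeat_flag = FALSE)
  validate_callset(out)
  out
}

#' Left-normalize variant records against a reference
#'
#' Produces the unique left-most minimal representation of each variant:
#' shared trailing bases are trimmed (extending left through the reference
#' when an allele would become empty, which shifts indels left through
#' repeat runs), then shared leading bases are trimmed while both alleles
#' keep at least one base. SNVs are returned unchanged. This matches the
#' normalization performed by `bcftools norm` / `vt normalize`.
#'
#' @param calls callset tibble
#' @param reference named character vector (or list) of chromosome
#'   sequences, names matching `chrom`
#' @return callset tibble with normalized `pos`, `ref`, `alt`
#' @export
left_normalize <- function(calls, reference) {
  if (nrow(calls) == 0) return(calls)
  reference <- lapply(reference, function(s) toupper(as.character(s)))
  for (i in seq_len(nrow(calls))) {
    chrom <- calls$chrom[i]
    if (is.null(reference[[chrom]])) {
      stop("reference missing chromosome ", chrom, call. = FALSE)
    }
    seq <- reference[[chrom]]
    pos <- calls$pos[i]; ref <- calls$ref[i]; alt <- calls$alt[i]
    if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
      stop(sprintf("REF mismatch at %s:%d: record %s vs reference %s",
                   chrom, pos, ref,
                   substr(seq, pos, pos + nchar(ref) - 1L)), call. = FALSE)
    }
    if (nchar(ref) == 1 && nchar(alt) == 1) next
    repeat {
      if (nchar(ref) > 0 && nchar(alt) > 0 &&
          substr(ref, nchar(ref), nchar(ref)) ==
          substr(alt, nchar(alt), nchar(alt)) &&
          (nchar(ref) > 1 || nchar(alt) > 1)) {
        ref <- substr(ref, 1, nchar(ref) - 1L)
        alt <- substr(alt, 1, nchar(alt) - 1L)
        if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos == 1) {
            stop("cannot left-extend past chromosome start at ",
                 chrom, ":1", call. = FALSE)
          }
          b <- substr(seq, pos - 1L, pos - 1L)
          ref <- paste0(b, ref); alt <- paste0(b, alt)
          pos <- pos - 1L
        }
      } else break
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    calls$pos[i] <- pos; calls$ref[i] <- ref; calls$alt[i] <- alt
  }
  calls
}

#' Canonical variant keys
#'
#' `chrom:pos:ref:alt` for each record. Two calls denote the same variant
#' iff their keys are equal, assuming both were normalized with
#' [left_normalize()] first.
#'
#' @param calls callset tibble
#' @return character vector of keys (`variant_key`), or the callset with a
#'   `key` column added (`add_variant_key`)
#' @export
variant_key <- function(calls) {
  sprintf("%s:%d:%s:%s", calls$chrom, as.integer(calls$pos),
          calls$ref, calls$alt)
}

#' @rdname variant_key
#' @export
add_variant_key <- function(calls) {
  calls$key <- variant_key(calls)
  calls
}

#' Restrict a callset to the panel target regions
#'
#' A call is retained iff its anchor base (`pos`, the left-most base of the
#' normalized record) falls inside a target interval.
#'
#' @param calls callset tibble (normalized)
#' @param design a `panel_design`
#' @return filtered callset
#' @export
restrict_to_targets <- function(calls, design) {
  if (nrow(calls) == 0) return(calls)
  calls[panel_contains(design, calls$chrom, calls$pos), , drop = FALSE]
}

#' Depth, allele-fraction and pipeline-filter callset filters
#'
#' `apply_depth_filter()` keeps calls with `depth >= min_depth` (the 10x
#' cutoff applied to both platforms; depth 10 passes).
#' `apply_af_filter()` drops calls of the listed platforms with
#' `alt_fraction < min_fraction` (the WES pipeline discards variants seen
#' in <20% of reads; a fraction of exactly 0.20 passes; other platforms are
#' untouched). `apply_pass_filter()` keeps calls whose upstream pipeline
#' filter (e.g. VQSR tranche) passed.
#'
#' @param calls callset tibble
#' @param min_depth minimum read depth (default 10)
#' @return filtered callset
#' @export
apply_depth_filter <- function(calls, min_depth = 10) {
  calls[calls$depth >= min_depth, , drop = FALSE]
}

#' @param min_fraction minimum alternate-read fraction (default 0.20)
#' @param platforms platforms the fraction filter applies to (default
#'   `"WES"`)
#' @rdname apply_depth_filter
#' @export
apply_af_filter <- function(calls, min_fraction = 0.20, platforms = "WES") {
  drop <- calls$platform %in% platforms &
    !is.na(calls$alt_fraction) & calls$alt_fraction < min_fraction
  calls[!drop, , drop = FALSE]
}

#' @rdname apply_depth_filter
#' @export
apply_pass_filter <- function(calls) {
  calls[calls$filter_pass, , drop = FALSE]
}

#' GC content of the reference window around a position
#'
#' Percent G+C in a window of `2 * half_window + 1` bases centered on `pos`
#' (clipped at sequence ends). Used to fill `gc_pct` when the input
#' annotation lacks it; the default 101 bp window plays the role of the
#' "variant region" GC measure used when flagging misalignment-prone loci.
#'
#' @param reference named character vector of chromosome sequences
#' @param chrom,pos vectors of chromosome / 1-based position
#' @param half_window bases on each side of the position (default 50)
#' @return numeric vector of GC percentages
#' @export
gc_content_pct <- function(reference, chrom, pos, half_window = 50) {
  reference <- lapply(reference, function(s) toupper(as.character(s)))
  mapply(function(cn, p) {
    seq <- reference[[cn]]
    if (is.null(seq)) return(NA_real_)
    lo <- max(1L, p - half_window)
    hi <- min(nchar(seq), p + half_window)
    w <- strsplit(substr(seq, lo, hi), "")[[1]]
    100 * mean(w %in% c("G", "C"))
  }, chrom, pos, USE.NAMES = FALSE)
}
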