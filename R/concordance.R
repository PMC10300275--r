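#' Compare the two platforms' callsets
#'
#' Key-based three-way partition of the union of variant keys: `shared`
#' (called by both platforms), `ts_only`, `wes_only`. Callsets are expected
#' to be normalized, target-restricted and filtered first. Per-variant
#' annotation (gene, rsid, ClinVar, MAF, CADD, GC, repeat flag) is carried
#' from the calling records (TS record preferred when both platforms call).
#'
#' @param ts_calls,wes_calls callset tibbles for the two platforms
#' @return a `comparison` object: list with `shared`, `ts_only`, `wes_only`
#'   (character key sets), `per_variant` (one row per key with `in_ts`,
#'   `in_wes` and annotation columns) and `calls` (the input records, keyed)
#' @export
compare_callsets <- function(ts_calls, wes_calls) {
  stopifnot(all(ts_calls$platform == "TS"), all(wes_calls$platform == "WES"))
  calls <- add_variant_key(dplyr::bind_rows(ts_calls, wes_calls))
  ts_keys <- unique(calls$key[calls$platform == "TS"])
  wes_keys <- unique(calls$key[calls$platform == "WES"])
  shared <- intersect(ts_keys, wes_keys)
  ann <- calls[!duplicated(calls$key),
               c("key", "chrom", "pos", "ref", "alt", "gene", "rsid",
                 "consequence", "clinvar_sig", "maf_exac_nfe", "cadd",
                 "gc_pct", "repeat_flag")]
  per_variant <- dplyr::mutate(ann,
                               in_ts = key %in% ts_keys,
                               in_wes = key %in% wes_keys)
  structure(
    list(shared = shared,
         ts_only = setdiff(ts_keys, wes_keys),
         wes_only = setdiff(wes_keys, ts_keys),
         per_variant = per_variant,
         calls = calls),
    class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison> %d keys: %d shared, %d TS-only, %d WES-only\n",
              nrow(x$per_variant), length(x$shared), length(x$ts_only),
              length(x$wes_only)))
  invisible(x)
}

#' Assign truth status from confirmation labels
#'
#' Variants called by both platforms are treated as true without orthogonal
#' testing (`true_shared`); platform-unique variants are adjudicated by
#' their Sanger confirmation label (`true_confirmed` /
#' `false_unconfirmed`). Unique variants without a label become `untested`
#' and are excluded from the metrics with a warning.
#'
#' @param cmp a `comparison` from [compare_callsets()]
#' @param sanger tibble with columns `key` and `confirmed` (logical)
#' @return the comparison with a `truth` column added to `per_variant`
#' @export
assign_truth <- function(cmp, sanger) {
  pv <- cmp$per_variant
  lab <- setNames(sanger$confirmed, sanger$key)
  unique_call <- xor(pv$in_ts, pv$in_wes)
  truth <- ifelse(pv$in_ts & pv$in_wes, "true_shared", NA)
  has_lab <- pv$key %in% names(lab)
  truth[unique_call & has_lab & lab[pv$key]] <- "true_confirmed"
  truth[unique_call & has_lab & !lab[pv$key]] <- "false_unconfirmed"
  truth[unique_call & !has_lab] <- "untested"
  if (any(truth == "untested", na.rm = TRUE)) {
    warning(sum(truth == "untested"),
            " platform-unique variant(s) without a confirmation label are ",
            "excluded from the metrics", call. = FALSE)
  }
  cmp$per_variant$truth <- truth
  cmp
}

truth_assigned <- function(cmp) {
  if (is.null(cmp$per_variant$truth)) {
    stop("truth not assigned; call assign_truth() first", call. = FALSE)
  }
  cmp$per_variant
}

platform_flag <- function(pv, platform) {
  switch(platform, TS = pv$in_ts, WES = pv$in_wes,
         stop("unknown platform: ", platform, call. = FALSE))
}

#' Detection rate of a platform
#'
#' Percentage of all true variants (dual-platform or confirmed unique) that
#' the platform called, reported to one decimal (half-up).
#'
#' @param cmp a truth-assigned `comparison`
#' @param platform `"TS"` or `"WES"`
#' @return percentage in `[0, 100]`
#' @export
detection_rate <- function(cmp, platform = c("TS", "WES")) {
  platform <- match.arg(platform)
  pv <- truth_assigned(cmp)
  true <- pv$truth %in% c("true_shared", "true_confirmed")
  if (!any(true)) stop("no true variants", call. = FALSE)
  round_half_up(100 * sum(true & platform_flag(pv, platform)) / sum(true), 1)
}

#' Specificity of a platform
#'
#' Percentage of the platform's calls (excluding untested ones) that are
#' true, reported to one decimal (half-up). Equals 100 whenever the
#' platform has no unconfirmed calls.
#'
#' @inheritParams detection_rate
#' @return percentage in `[0, 100]`
#' @export
specificity <- function(cmp, platform = c("TS", "WES")) {
  platform <- match.arg(platform)
  pv <- truth_assigned(cmp)
  called <- platform_flag(pv, platform) & pv$truth != "untested"
  if (!any(called)) stop("no calls for platform ", platform, call. = FALSE)
  true <- pv$truth %in% c("true_shared", "true_confirmed")
  round_half_up(100 * sum(called & true) / sum(called), 1)
}

#' Detection-rate and specificity metrics for both platforms
#'
#' @inheritParams detection_rate
#' @return list with `metrics` (tibble: platform, detection_rate,
#'   specificity) and `counts` (total_true and per-platform true/false/call
#'   counts)
#' @export
concordance_metrics <- function(cmp) {
  pv <- truth_assigned(cmp)
  true <- pv$truth %in% c("true_shared", "true_confirmed")
  counts <- list(total_true = sum(true))
  for (p in c("TS", "WES")) {
    called <- platform_flag(pv, p) & pv$truth != "untested"
    counts[[paste0("true_", p)]] <- sum(called & true)
    counts[[paste0("false_", p)]] <- sum(called & pv$truth == "false_unconfirmed")
    counts[[paste0("calls_", p)]] <- sum(called)
  }
  list(metrics = tibble::tibble(
    platform = c("TS", "WES"),
    detection_rate = c(detection_rate(cmp, "TS"), detection_rate(cmp, "WES")),
    specificity = c(specificity(cmp, "TS"), specificity(cmp, "WES"))),
    counts = counts)
}

#' Three-set summary with integer percentages
#'
#' Counts of variants detected by both platforms, by TS only and by WES
#' only, with percentages of the total rounded half-up to integers.
#'
#' @param both,ts_only,wes_only counts, or pass a `comparison` as `both`
#' @return list with `counts` and `pct` (named: both, ts_only, wes_only,
#'   total)
#' @export
#' @examples
#' venn_summary(288, 66, 20)
venn_summary <- function(both, ts_only = NULL, wes_only = NULL) {
  if (inherits(both, "comparison")) {
    cmp <- both
    both <- length(cmp$shared)
    ts_only <- length(cmp$ts_only)
    wes_only <- length(cmp$wes_only)
  }
  total <- both + ts_only + wes_only
  counts <- c(both = both, ts_only = ts_only, wes_only = wes_only,
              total = total)
  pct <- if (total > 0) {
    round_half_up(100 * counts[1:3] / total)
  } else c(both = 0, ts_only = 0, wes_only = 0)
  list(counts = counts, pct = pct)
}

DISCREPANCY_REASONS <- c("insufficient_coverage_other_platform",
                         "pipeline_filter_fail",
                         "false_positive_misalignment", "unexplained")

depth_at_locus <- function(tracks, platform, sample_ids, chrom, pos) {
  sel <- tracks$platform == platform & tracks$sample_id %in% sample_ids &
    tracks$chrom == chrom & tracks$pos0 == pos - 1L
  if (!any(sel)) return(0)
  mean(tracks$depth[sel])
}

#' Assign a discrepancy reason to each platform-unique variant
#'
#' Fixed decision cascade per unique variant, evaluated in the carrier
#' sample(s) where the calling platform saw it:
#' 1. depth of the *non-calling* platform's track at the locus below
#'    `reason_depth_threshold` (absent locus counts as 0) ->
#'    `insufficient_coverage_other_platform`;
#' 2. else, the non-calling platform produced a record at the key that
#'    failed its pipeline filter -> `pipeline_filter_fail`;
#' 3. else, the variant is unconfirmed and its locus is
#'    misalignment-prone (GC >= `gc_misalign` percent or `repeat_flag`) ->
#'    `false_positive_misalignment`;
#' 4. else `unexplained`.
#'
#' `reason_depth_threshold` defaults to the 10x calling cutoff but is
#' configurable: published discrepancy tables sometimes label loci with
#' 10-15x as insufficiently covered, so a stricter value (e.g. 20) can be
#' supplied.
#'
#' @param cmp a truth-assigned `comparison`
#' @param tracks depth-track tibble covering both platforms
#' @param raw_calls optional unfiltered callset (both platforms) used to
#'   detect filter-failed records of the non-calling platform
#' @param reason_depth_threshold depth below which the other platform's
#'   coverage counts as insufficient (default 10)
#' @param gc_misalign GC percentage at or above which an unconfirmed call
#'   is attributed to misalignment (default 70)
#' @return the comparison with a `reason` column on `per_variant` (NA for
#'   shared variants)
#' @export
assign_discrepancy_reason <- function(cmp, tracks, raw_calls = NULL,
                                      reason_depth_threshold = 10,
                                      gc_misalign = 70) {
  pv <- truth_assigned(cmp)
  reason <- rep(NA_character_, nrow(pv))
  raw <- if (!is.null(raw_calls)) add_variant_key(raw_calls) else cmp$calls
  for (i in which(xor(pv$in_ts, pv$in_wes))) {
    caller <- if (pv$in_ts[i]) "TS" else "WES"
    other <- if (caller == "TS") "WES" else "TS"
    carriers <- unique(cmp$calls$sample_id[cmp$calls$key == pv$key[i] &
                                             cmp$calls$platform == caller])
    d <- depth_at_locus(tracks, other, carriers, pv$chrom[i], pv$pos[i])
    if (d < reason_depth_threshold) {
      reason[i] <- "insufficient_coverage_other_platform"
    } else if (any(raw$key == pv$key[i] & raw$platform == other &
                     !raw$filter_pass)) {
      reason[i] <- "pipeline_filter_fail"
    } else if (identical(pv$truth[i], "false_unconfirmed") &&
               ((!is.na(pv$gc_pct[i]) && pv$gc_pct[i] >= gc_misalign) ||
                isTRUE(pv$repeat_flag[i]))) {
      reason[i] <- "false_positive_misalignment"
    } else {
      reason[i] <- "unexplained"
    }
  }
  cmp$per_variant$reason <- reason
  cmp
}
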