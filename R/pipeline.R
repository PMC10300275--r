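#' Pipeline configuration
#'
#' Collects every threshold the pipeline applies, at its default: 10x
#' calling depth, 20% minimum WES alternate-read fraction, the HFI MAF/CADD
#' cutoffs, the discrepancy-reason depth threshold and the GC percentage
#' marking misalignment-prone sequence.
#'
#' @param min_depth calling depth cutoff (calls with depth >= this pass)
#' @param min_af minimum WES alternate-read fraction
#' @param maf_rare,maf_max,cadd_min HFI cascade thresholds, see
#'   [hfi_thresholds()]
#' @param reason_depth_threshold depth under which the non-calling
#'   platform's coverage counts as insufficient when explaining a
#'   discrepancy
#' @param gc_misalign GC percent at or above which an unconfirmed unique
#'   call is attributed to misalignment
#' @param coverage_threshold depth threshold for the coverage summary
#' @param hfi_only compute concordance metrics over the HFI universe
#'   (default) or over all variants
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(min_depth = 10, min_af = 0.20,
                            maf_rare = 0.005, maf_max = 0.05, cadd_min = 20,
                            reason_depth_threshold = 10, gc_misalign = 70,
                            coverage_threshold = 10, hfi_only = TRUE) {
  stopifnot(min_depth > 0, min_af > 0, reason_depth_threshold > 0,
            gc_misalign > 0, coverage_threshold > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Stages, in order: restrict both callsets to the panel targets; apply the
#' platform pipeline filter, the depth cutoff and the WES allele-fraction
#' filter; summarise coverage; triage variants into the HFI class; compare
#' callsets (all variants and the HFI subset); assign truth from the
#' confirmation labels; assign discrepancy reasons; compute detection rate
#' and specificity. Every percentage in the report is recomputable from
#' integer counts also present in it.
#'
#' @param design a `panel_design`
#' @param tracks depth-track tibble, both platforms
#' @param ts_calls,wes_calls annotated callsets (normalized)
#' @param sanger confirmation-label tibble (`key`, `confirmed`)
#' @param config a [pipeline_config()]
#' @return a `pipeline_report` list: `coverage`, `hfi`, `comparison_all`,
#'   `venn_all`, `comparison_hfi`, `venn_hfi`, `metrics`,
#'   `discrepancies`, `config`
#' @export
run_pipeline <- function(design, tracks, ts_calls, wes_calls, sanger,
                         config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  filt <- function(calls) {
    calls |> restrict_to_targets(design) |> apply_pass_filter() |>
      apply_depth_filter(config$min_depth) |>
      apply_af_filter(config$min_af, platforms = "WES")
  }
  ts_f <- stage("filter TS callset", filt(ts_calls))
  wes_f <- stage("filter WES callset", filt(wes_calls))
  coverage <- stage("coverage summary",
                    coverage_summary(tracks, design,
                                     config$coverage_threshold))
  thr <- hfi_thresholds(config$maf_rare, config$maf_max, config$cadd_min)
  hfi_ts <- stage("HFI triage TS", classify_callset(ts_f, thr))
  hfi_wes <- stage("HFI triage WES", classify_callset(wes_f, thr))

  cmp_all <- stage("compare callsets", compare_callsets(ts_f, wes_f))
  venn_all <- venn_summary(cmp_all)

  if (nrow(hfi_ts$hfi) + nrow(hfi_wes$hfi) == 0) {
    cmp_hfi <- NULL; venn_hfi <- NULL; metrics <- NULL; disc <- NULL
  } else {
    cmp_hfi <- stage("compare HFI callsets",
                     compare_callsets(hfi_ts$hfi, hfi_wes$hfi))
    cmp_metric <- if (config$hfi_only) cmp_hfi else cmp_all
    cmp_metric <- stage("assign truth", assign_truth(cmp_metric, sanger))
    cmp_metric <- stage("assign discrepancy reasons",
                        assign_discrepancy_reason(
                          cmp_metric, tracks,
                          raw_calls = dplyr::bind_rows(ts_calls, wes_calls),
                          reason_depth_threshold =
                            config$reason_depth_threshold,
                          gc_misalign = config$gc_misalign))
    cmp_hfi <- cmp_metric
    venn_hfi <- venn_summary(cmp_hfi)
    metrics <- stage("concordance metrics", concordance_metrics(cmp_hfi))
    disc <- stage("discrepancy table",
                  discrepancy_table(cmp_hfi, tracks))
  }
  structure(list(coverage = coverage,
                 hfi = list(TS = hfi_ts, WES = hfi_wes),
                 comparison_all = cmp_all, venn_all = venn_all,
                 comparison_hfi = cmp_hfi, venn_hfi = venn_hfi,
                 metrics = metrics, discrepancies = disc,
                 config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  v <- x$venn_all$counts
  cat(sprintf("  all variants: %d (%d shared / %d TS-only / %d WES-only)\n",
              v[["total"]], v[["both"]], v[["ts_only"]], v[["wes_only"]]))
  if (!is.null(x$venn_hfi)) {
    v <- x$venn_hfi$counts
    cat(sprintf("  HFI variants: %d (%d shared / %d TS-only / %d WES-only)\n",
                v[["total"]], v[["both"]], v[["ts_only"]], v[["wes_only"]]))
  }
  if (!is.null(x$metrics)) print(x$metrics$metrics)
  invisible(x)
}

#' Per-variant discrepancy table
#'
#' One row per platform-unique variant, mirroring the columns of a
#' published discrepancy table: gene, variant identifiers, consequence,
#' ClinVar significance, CADD, population MAF, confirmation status, GC
#' content, sequencing depth in the detecting and the other platform, and
#' the assigned reason.
#'
#' @param cmp a truth- and reason-assigned `comparison`
#' @param tracks depth-track tibble
#' @return tibble, one row per unique variant
#' @export
discrepancy_table <- function(cmp, tracks) {
  pv <- truth_assigned(cmp)
  rows <- lapply(which(xor(pv$in_ts, pv$in_wes)), function(i) {
    caller <- if (pv$in_ts[i]) "TS" else "WES"
    other <- if (caller == "TS") "WES" else "TS"
    rec <- cmp$calls[cmp$calls$key == pv$key[i] &
                       cmp$calls$platform == caller, ][1, ]
    tibble::tibble(
      gene = pv$gene[i], rsid = pv$rsid[i], key = pv$key[i],
      platform = caller,
      consequence = pv$consequence[i], clinvar_sig = pv$clinvar_sig[i],
      cadd = pv$cadd[i], maf_exac_nfe = pv$maf_exac_nfe[i],
      confirmation = switch(pv$truth[i],
                            true_confirmed = "Confirmed",
                            false_unconfirmed = "Not confirmed",
                            pv$truth[i]),
      gc_pct = pv$gc_pct[i],
      depth_detecting = rec$depth,
      depth_other = depth_at_locus(tracks, other, rec$sample_id,
                                   pv$chrom[i], pv$pos[i]),
      reason = pv$reason[i])
  })
  dplyr::bind_rows(rows)
}

#' Render the report's tables to files
#'
#' Writes, under `dir`: `coverage_per_sample.tsv` (one row per sample and
#' platform plus `mean` and `sd` summary rows, depths and percentages
#' rounded to integers), `coverage_per_gene.tsv`, `discrepancies.tsv`,
#' `venn.tsv` and `metrics.json`.
#'
#' @param report a `pipeline_report`
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ps <- report$coverage$per_sample
  wide <- merge(
    ps[ps$platform == "TS", c("sample_id", "mean_depth", "pct_at_threshold")],
    ps[ps$platform == "WES", c("sample_id", "mean_depth", "pct_at_threshold")],
    by = "sample_id", suffixes = c("_TS", "_WES"), all = TRUE)
  num <- names(wide)[-1]
  tab <- rbind(
    cbind(sample = wide$sample_id,
          as.data.frame(lapply(wide[num], round_half_up))),
    cbind(sample = "mean",
          as.data.frame(lapply(wide[num], function(v)
            round_half_up(mean(v, na.rm = TRUE))))),
    cbind(sample = "sd",
          as.data.frame(lapply(wide[num], function(v)
            round_half_up(stats::sd(v, na.rm = TRUE))))))
  f <- file.path(dir, "coverage_per_sample.tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(dir, "coverage_per_gene.tsv")
  write.table(report$coverage$per_gene, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)

  if (!is.null(report$discrepancies)) {
    f <- file.path(dir, "discrepancies.tsv")
    write.table(report$discrepancies, f, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    files <- c(files, f)
  }

  venn_row <- function(label, v) {
    data.frame(set = label,
               both = v$counts[["both"]], ts_only = v$counts[["ts_only"]],
               wes_only = v$counts[["wes_only"]], total = v$counts[["total"]],
               pct_both = v$pct[["both"]], pct_ts_only = v$pct[["ts_only"]],
               pct_wes_only = v$pct[["wes_only"]])
  }
  venn <- venn_row("all", report$venn_all)
  if (!is.null(report$venn_hfi)) {
    venn <- rbind(venn, venn_row("hfi", report$venn_hfi))
  }
  f <- file.path(dir, "venn.tsv")
  write.table(venn, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(report$metrics)) {
    f <- file.path(dir, "metrics.json")
    jsonlite::write_json(list(metrics = report$metrics$metrics,
                              counts = report$metrics$counts),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
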