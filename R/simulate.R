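#' Simulation configuration
#'
#' Parameters of the synthetic paired-platform experiment. The defaults
#' emulate the validation cohort's statistical structure: 19 samples, a
#' panel-style TS assay with deep but highly variable coverage (per-sample
#' mean depth lognormal with mean 300x, sd 190x) against an exome with
#' shallower, tight coverage (truncated normal, mean 102x, sd 7x); per-base
#' dispersion around the sample mean is negative-binomial. Planted dropout
#' segments (depth < 10) cover about 3% of target bases for TS and 13% for
#' WES, the latter preferentially in GC-rich exons, so that roughly 97% and
#' 87% of target bases are covered at 10x. The default planted callset
#' decomposition is 89 shared true / 4 TS-only true (half missed by WES for
#' coverage, half lost to the WES pipeline filter) / 3 WES-only true
#' (missed by TS for coverage) / 2 TS false positives in
#' misalignment-prone sequence, plus synonymous background variants shared
#' by both platforms.
#'
#' @param seed integer seed governing every stage through one generator
#'   stream
#' @param n_genes,exons_per_gene,exon_length panel geometry;
#'   `exons_per_gene` and `exon_length` are inclusive ranges
#' @param n_samples number of paired samples
#' @param ts_depth_mean,ts_depth_sd lognormal per-sample TS mean depth
#' @param wes_depth_mean,wes_depth_sd truncated-normal per-sample WES mean
#'   depth
#' @param depth_dispersion negative-binomial size of per-base depth around
#'   the sample mean
#' @param dropout_rate_ts,dropout_rate_wes fraction of target bases planted
#'   as dropout (depth < 10) per platform
#' @param gc_rich_fraction fraction of exons flagged GC-rich (preferred WES
#'   dropout sites)
#' @param planted named counts `shared_true`, `ts_only_true`,
#'   `wes_only_true`, `ts_false_positives`, `wes_false_positives` of
#'   planted HFI variants
#' @param filter_fail_rate_wes fraction of TS-only true variants made
#'   invisible to WES via a failed pipeline-filter record (the rest via
#'   forced low WES depth)
#' @param n_background number of shared synonymous (non-HFI) background
#'   variants
#' @param flank exon flank width passed to [build_targets()]
#' @return a `sim_config` list
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 12, exons_per_gene = c(4, 8),
                              exon_length = c(120, 220), n_samples = 19,
                              ts_depth_mean = 300, ts_depth_sd = 190,
                              wes_depth_mean = 102, wes_depth_sd = 7,
                              depth_dispersion = 8,
                              dropout_rate_ts = 0.03,
                              dropout_rate_wes = 0.13,
                              gc_rich_fraction = 0.15,
                              planted = c(shared_true = 89, ts_only_true = 4,
                                          wes_only_true = 3,
                                          ts_false_positives = 2,
                                          wes_false_positives = 0),
                              filter_fail_rate_wes = 0.5,
                              n_background = 60,
                              flank = 25) {
  need <- c("shared_true", "ts_only_true", "wes_only_true",
            "ts_false_positives", "wes_false_positives")
  stopifnot(all(need %in% names(planted)), all(planted >= 0),
            n_genes >= 1, n_samples >= 1,
            dropout_rate_ts >= 0, dropout_rate_ts <= 1,
            dropout_rate_wes >= 0, dropout_rate_wes <= 1,
            filter_fail_rate_wes >= 0, filter_fail_rate_wes <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a toy panel design
#'
#' Genes are laid out deterministically (given the seed) over at least two
#' chromosomes, cycling through the six panel categories, with exons
#' separated by intron gaps so genes can never overlap. Exons are flagged
#' `gc_rich` at the configured fraction (these attract WES dropouts).
#'
#' @param cfg a `sim_config`
#' @return a `panel_design` whose `exons` carry a `gc_rich` flag
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(max(2, min(4, ceiling(cfg$n_genes / 3)))))
  cats <- panel_categories()
  cursor <- setNames(rep(10000L, length(chroms)), chroms)
  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    cn <- chroms[(g - 1L) %% length(chroms) + 1L]
    n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
    start <- cursor[cn]
    ex <- vector("list", n_ex)
    for (e in seq_len(n_ex)) {
      len <- sample(cfg$exon_length[1]:cfg$exon_length[2], 1)
      ex[[e]] <- c(start, start + len)
      start <- start + len + sample(300:800, 1)
    }
    cursor[cn] <- start + 5000L
    rows[[g]] <- tibble::tibble(
      gene = sprintf("GENE%02d", g),
      category = cats[(g - 1L) %% 6 + 1L],
      chrom = cn,
      start = vapply(ex, `[`, 0, 1),
      end = vapply(ex, `[`, 0, 2),
      region_type = "exon")
  }
  genes <- dplyr::bind_rows(rows)
  design <- build_targets(genes, flank = cfg$flank)
  n_ex <- nrow(design$exons)
  gc_rich <- rep(FALSE, n_ex)
  gc_rich[sample.int(n_ex, max(1L, round(cfg$gc_rich_fraction * n_ex)))] <- TRUE
  design$exons$gc_rich <- gc_rich
  design
}

# enumerate every target base as (chrom, pos0)
target_bases <- function(design) {
  t <- design$targets
  idx <- rep.int(seq_len(nrow(t)), t$end - t$start)
  tibble::tibble(chrom = t$chrom[idx],
                 pos0 = unlist(lapply(seq_len(nrow(t)), function(i)
                   seq.int(t$start[i], t$end[i] - 1L))))
}

# indices of `bases` rows falling in each flanked exon
exon_base_index <- function(design, bases) {
  fl <- design$exons
  fl$start <- pmax(0L, fl$start - design$flank)
  fl$end <- fl$end + design$flank
  lapply(seq_len(nrow(fl)), function(i) {
    which(bases$chrom == fl$chrom[i] & bases$pos0 >= fl$start[i] &
            bases$pos0 < fl$end[i])
  })
}

#' Simulate per-base depth tracks for both platforms
#'
#' For each sample, a platform-level mean depth is drawn (TS: lognormal;
#' WES: truncated normal), per-base depths are negative-binomial around it,
#' and dropout segments are planted exon-by-exon until the configured
#' fraction of target bases sits below 10x (WES dropouts prefer GC-rich
#' exons; the last exon is truncated so the planted fraction is met
#' exactly, up to rounding).
#'
#' @param cfg a `sim_config`
#' @param design the `panel_design` from [simulate_panel()]
#' @return depth-track tibble for all samples and both platforms
#' @export
simulate_depth <- function(cfg, design) {
  bases <- target_bases(design)
  L <- nrow(bases)
  if (L == 0) stop("empty design", call. = FALSE)
  ex_idx <- exon_base_index(design, bases)
  gc_rich <- design$exons$gc_rich %||% rep(FALSE, length(ex_idx))
  sdlog_ts <- sqrt(log(1 + (cfg$ts_depth_sd / cfg$ts_depth_mean)^2))
  meanlog_ts <- log(cfg$ts_depth_mean) - sdlog_ts^2 / 2
  out <- vector("list", 2L * cfg$n_samples)
  k <- 0L
  for (s in seq_len(cfg$n_samples)) {
    sid <- sprintf("S%02d", s)
    for (p in c("TS", "WES")) {
      mu <- if (p == "TS") rlnorm(1, meanlog_ts, sdlog_ts)
            else max(20, rnorm(1, cfg$wes_depth_mean, cfg$wes_depth_sd))
      rate <- if (p == "TS") cfg$dropout_rate_ts else cfg$dropout_rate_wes
      # dropout bases average ~4.5x; inflate the non-dropout mean so the
      # realized track mean stays at the drawn sample mean
      mu_adj <- if (rate < 1) max(1, (mu - rate * 4.5) / (1 - rate)) else mu
      depth <- rnbinom(L, mu = mu_adj, size = cfg$depth_dispersion)
      budget <- round(rate * L)
      if (budget > 0) {
        ord <- if (p == "WES") {
          c(sample(which(gc_rich)), sample(which(!gc_rich)))
        } else sample(seq_along(ex_idx))
        dropped <- integer(0)
        for (e in ord) {
          if (length(dropped) >= budget) break
          take <- ex_idx[[e]]
          need <- budget - length(dropped)
          if (length(take) > need) take <- take[seq_len(need)]
          dropped <- c(dropped, take)
        }
        depth[unique(dropped)] <- sample(0:9, length(unique(dropped)),
                                         replace = TRUE)
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(sample_id = sid, platform = p,
                                 chrom = bases$chrom, pos0 = bases$pos0,
                                 depth = as.integer(depth))
    }
  }
  dplyr::bind_rows(out)
}

sample_hfi_annotation <- function(n, criterion) {
  non_plp <- c("Uncertain", "Not_found", "Likely_benign", "Benign",
               "Conflicting")
  cons <- sample(c("missense_variant", "stopgain", "nonsynonymous SNV",
                   "Exonic non-synonymous"), n, replace = TRUE)
  clin <- character(n); maf <- numeric(n); cadd <- numeric(n)
  for (i in seq_len(n)) {
    if (criterion[i] == "A_clinvar_plp") {
      clin[i] <- sample(c("Pathogenic", "Likely_pathogenic"), 1)
      maf[i] <- runif(1, 0, 0.05); cadd[i] <- runif(1, 0, 40)
    } else if (criterion[i] == "B_rare_vus") {
      clin[i] <- sample(non_plp, 1)
      maf[i] <- if (runif(1) < 0.5) 0 else runif(1, 0, 0.0049)
      cadd[i] <- runif(1, 0, 40)
    } else {
      clin[i] <- sample(non_plp, 1)
      maf[i] <- runif(1, 0.006, 0.049); cadd[i] <- runif(1, 20.5, 40)
    }
  }
  tibble::tibble(consequence = cons, clinvar_sig = clin,
                 maf_exac_nfe = maf, cadd = cadd)
}

force_track_depth <- function(tracks, sample_id, platform, chrom, pos,
                              value = NULL, min_value = NULL) {
  sel <- which(tracks$sample_id == sample_id & tracks$platform == platform &
                 tracks$chrom == chrom & tracks$pos0 == pos - 1L)
  if (!length(sel)) return(tracks)
  if (!is.null(value)) tracks$depth[sel] <- as.integer(value)
  if (!is.null(min_value)) {
    tracks$depth[sel] <- pmax(tracks$depth[sel], as.integer(min_value))
  }
  tracks
}

#' Simulate paired annotated callsets with planted ground truth
#'
#' Places the configured numbers of shared, platform-unique and
#' false-positive variants (all SNVs) at distinct covered exonic positions,
#' draws their annotations so the intended HFI criterion is realized by
#' construction, and makes platform-unique variants invisible to the other
#' platform by the intended mechanism: depth forced below 10 at the locus
#' (coverage), or a filter-failed WES record (pipeline filter). Planted
#' false positives get misalignment-compatible annotation (GC >= 70 or a
#' repeat flag) and a "not confirmed" Sanger label; all other unique
#' variants are labeled confirmed. Depth at every calling platform's locus
#' is forced to at least 30 so planted calls always survive the 10x filter.
#'
#' @param cfg a `sim_config`
#' @param design the simulated `panel_design`
#' @param tracks depth tracks from [simulate_depth()] (modified copies are
#'   returned: planting edits depths at variant loci)
#' @return list with `ts_calls`, `wes_calls`, `sanger` (key/confirmed),
#'   `truth` (per-variant planted record) and the updated `tracks`
#' @export
simulate_callsets <- function(cfg, design, tracks) {
  pl <- cfg$planted
  n_true <- pl[["shared_true"]] + pl[["ts_only_true"]] + pl[["wes_only_true"]]
  if (n_true == 0) stop("no truth universe", call. = FALSE)
  n_var <- n_true + pl[["ts_false_positives"]] +
    pl[["wes_false_positives"]] + cfg$n_background
  ex <- design$exons
  ex_bases <- tibble::tibble(
    chrom = rep(ex$chrom, ex$end - ex$start),
    pos0 = unlist(lapply(seq_len(nrow(ex)), function(i)
      seq.int(ex$start[i], ex$end[i] - 1L))))
  ex_bases <- dplyr::distinct(ex_bases)
  if (nrow(ex_bases) < n_var) {
    stop("insufficient covered positions for requested variant count",
         call. = FALSE)
  }
  loci <- ex_bases[sample.int(nrow(ex_bases), n_var), , drop = FALSE]

  category <- c(rep("shared_true", pl[["shared_true"]]),
                rep("ts_only_true", pl[["ts_only_true"]]),
                rep("wes_only_true", pl[["wes_only_true"]]),
                rep("ts_fp", pl[["ts_false_positives"]]),
                rep("wes_fp", pl[["wes_false_positives"]]),
                rep("background", cfg$n_background))
  n_ff <- round(cfg$filter_fail_rate_wes * pl[["ts_only_true"]])
  mechanism <- rep("none", n_var)
  mechanism[category == "ts_only_true"] <-
    c(rep("filter_fail", n_ff),
      rep("coverage", pl[["ts_only_true"]] - n_ff))
  mechanism[category == "wes_only_true"] <- "coverage"
  mechanism[category %in% c("ts_fp", "wes_fp")] <- "misalignment"

  bases4 <- c("A", "C", "G", "T")
  ref <- sample(bases4, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases4, r), 1), "")
  carrier <- sprintf("S%02d", sample.int(cfg$n_samples, n_var,
                                         replace = TRUE))
  is_hfi_var <- category != "background"
  criterion <- rep("none", n_var)
  criterion[is_hfi_var] <- sample(c("A_clinvar_plp", "B_rare_vus",
                                    "C_midfreq_cadd"), sum(is_hfi_var),
                                  replace = TRUE, prob = c(0.2, 0.6, 0.2))
  ann <- tibble::tibble(consequence = rep("synonymous SNV", n_var),
                        clinvar_sig = "Not_found",
                        maf_exac_nfe = runif(n_var, 0, 0.3),
                        cadd = runif(n_var, 0, 10))
  ann[is_hfi_var, ] <- sample_hfi_annotation(sum(is_hfi_var),
                                             criterion[is_hfi_var])
  gc_pct <- runif(n_var, 35, 65)
  repeat_flag <- rep(FALSE, n_var)
  fp <- which(category %in% c("ts_fp", "wes_fp"))
  for (j in seq_along(fp)) {
    if (j %% 2 == 1) gc_pct[fp[j]] <- runif(1, 70, 90)
    else repeat_flag[fp[j]] <- TRUE
  }

  pos <- loci$pos0 + 1L
  make_call <- function(i, platform, filter_pass = TRUE) {
    tibble::tibble(
      sample_id = carrier[i], platform = platform, chrom = loci$chrom[i],
      pos = pos[i], ref = ref[i], alt = alt[i],
      depth = NA_integer_, alt_fraction = round(runif(1, 0.3, 0.7), 3),
      filter_pass = filter_pass, rsid = NA_character_,
      consequence = ann$consequence[i], clinvar_sig = ann$clinvar_sig[i],
      maf_exac_nfe = ann$maf_exac_nfe[i], cadd = ann$cadd[i],
      gene = locus_gene(design, loci$chrom[i], loci$pos0[i]),
      gc_pct = round(gc_pct[i], 1), repeat_flag = repeat_flag[i])
  }
  ts_rows <- list(); wes_rows <- list()
  for (i in seq_len(n_var)) {
    calls_ts <- category[i] %in% c("shared_true", "ts_only_true", "ts_fp",
                                   "background")
    calls_wes <- category[i] %in% c("shared_true", "wes_only_true", "wes_fp",
                                    "background")
    if (calls_ts) {
      tracks <- force_track_depth(tracks, carrier[i], "TS", loci$chrom[i],
                                  pos[i], min_value = 30)
      ts_rows[[length(ts_rows) + 1L]] <- make_call(i, "TS")
    }
    if (calls_wes) {
      tracks <- force_track_depth(tracks, carrier[i], "WES", loci$chrom[i],
                                  pos[i], min_value = 30)
      wes_rows[[length(wes_rows) + 1L]] <- make_call(i, "WES")
    }
    if (mechanism[i] == "coverage") {
      other <- if (category[i] == "ts_only_true") "WES" else "TS"
      tracks <- force_track_depth(tracks, carrier[i], other, loci$chrom[i],
                                  pos[i], value = sample(0:9, 1))
    }
    if (mechanism[i] == "filter_fail") {
      tracks <- force_track_depth(tracks, carrier[i], "WES", loci$chrom[i],
                                  pos[i], min_value = 30)
      wes_rows[[length(wes_rows) + 1L]] <- make_call(i, "WES",
                                                     filter_pass = FALSE)
    }
    if (mechanism[i] == "misalignment") {
      other <- if (category[i] == "ts_fp") "WES" else "TS"
      tracks <- force_track_depth(tracks, carrier[i], other, loci$chrom[i],
                                  pos[i], min_value = 30)
    }
  }
  fill_depth <- function(calls) {
    if (!length(calls)) {
      return(tibble::as_tibble(setNames(rep(list(character(0)),
                                            length(CALLSET_COLUMNS)),
                                        CALLSET_COLUMNS)))
    }
    d <- dplyr::bind_rows(calls)
    for (r in seq_len(nrow(d))) {
      sel <- tracks$sample_id == d$sample_id[r] &
        tracks$platform == d$platform[r] & tracks$chrom == d$chrom[r] &
        tracks$pos0 == d$pos[r] - 1L
      d$depth[r] <- as.integer(tracks$depth[which(sel)[1]])
    }
    d
  }
  ts_calls <- fill_depth(ts_rows)
  wes_calls <- fill_depth(wes_rows)
  key <- sprintf("%s:%d:%s:%s", loci$chrom, pos, ref, alt)
  uniq <- category %in% c("ts_only_true", "wes_only_true", "ts_fp", "wes_fp")
  sanger <- tibble::tibble(
    key = key[uniq],
    confirmed = category[uniq] %in% c("ts_only_true", "wes_only_true"))
  truth <- tibble::tibble(key = key, category = category,
                          mechanism = mechanism, criterion = criterion,
                          carrier = carrier, chrom = loci$chrom, pos = pos)
  list(ts_calls = ts_calls, wes_calls = wes_calls, sanger = sanger,
       truth = truth, tracks = tracks)
}

locus_gene <- function(design, chrom, pos0) {
  p <- design$provenance
  hit <- which(p$chrom == chrom & pos0 >= p$start & pos0 < p$end)
  if (length(hit)) p$gene[hit[1]] else NA_character_
}

#' Simulate a full experiment (panel, depths, callsets) from one seed
#'
#' @param cfg a `sim_config`
#' @return list with `design`, `tracks`, and the [simulate_callsets()]
#'   outputs
#' @export
simulate_experiment <- function(cfg) {
  design <- simulate_panel(cfg)  # seeds the single generator stream
  tracks <- simulate_depth(cfg, design)
  cs <- simulate_callsets(cfg, design, tracks)
  c(list(design = design), cs)
}

#' Run the full pipeline on a simulated experiment and check recovery
#'
#' Simulates an experiment, pushes it through [run_pipeline()], and
#' compares the recovered HFI set decomposition and per-platform
#' (TP, FP, FN) counts with the planted truth; detection-rate expectations
#' come from direct arithmetic on the planted counts.
#'
#' @param cfg a `sim_config`
#' @param config pipeline thresholds, see [pipeline_config()]
#' @return list with `report` (the pipeline report), `planted`,
#'   `recovered`, `expected_metrics` and `ok` (exact count recovery)
#' @export
run_recovery <- function(cfg, config = pipeline_config()) {
  sim <- simulate_experiment(cfg)
  report <- run_pipeline(sim$design, sim$tracks, sim$ts_calls,
                         sim$wes_calls, sim$sanger, config)
  pl <- cfg$planted
  planted <- list(
    shared_hfi = pl[["shared_true"]],
    ts_only_hfi = pl[["ts_only_true"]] + pl[["ts_false_positives"]],
    wes_only_hfi = pl[["wes_only_true"]] + pl[["wes_false_positives"]],
    tp_ts = pl[["shared_true"]] + pl[["ts_only_true"]],
    fp_ts = pl[["ts_false_positives"]],
    fn_ts = pl[["wes_only_true"]],
    tp_wes = pl[["shared_true"]] + pl[["wes_only_true"]],
    fp_wes = pl[["wes_false_positives"]],
    fn_wes = pl[["ts_only_true"]])
  cnt <- report$metrics$counts
  recovered <- list(
    shared_hfi = unname(report$venn_hfi$counts[["both"]]),
    ts_only_hfi = unname(report$venn_hfi$counts[["ts_only"]]),
    wes_only_hfi = unname(report$venn_hfi$counts[["wes_only"]]),
    tp_ts = cnt$true_TS, fp_ts = cnt$false_TS,
    fn_ts = cnt$total_true - cnt$true_TS,
    tp_wes = cnt$true_WES, fp_wes = cnt$false_WES,
    fn_wes = cnt$total_true - cnt$true_WES)
  n_true <- pl[["shared_true"]] + pl[["ts_only_true"]] + pl[["wes_only_true"]]
  expected_metrics <- tibble::tibble(
    platform = c("TS", "WES"),
    detection_rate = round_half_up(
      100 * c(pl[["shared_true"]] + pl[["ts_only_true"]],
              pl[["shared_true"]] + pl[["wes_only_true"]]) / n_true, 1),
    specificity = round_half_up(
      100 * c(planted$tp_ts / (planted$tp_ts + planted$fp_ts),
              planted$tp_wes / (planted$tp_wes + planted$fp_wes)), 1))
  list(report = report, planted = planted, recovered = recovered,
       expected_metrics = expected_metrics,
       ok = identical(lapply(planted, as.integer),
                      lapply(recovered, as.integer)))
}
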