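#' Depth tracks
#'
#' Per-base sequencing depth over the panel target base set, stored long:
#' one tibble with columns `sample_id`, `platform` (`"TS"` or `"WES"`),
#' `chrom`, `pos0` (0-based position) and `depth`. Positions absent from a
#' track are treated as depth 0 everywhere in this module.
#'
#' @param path tab-separated file with header columns `chrom`, `pos`
#'   (1-based, the common depth-tool dialect) and `depth`
#' @param sample_id,platform identity of the track being read
#' @return depth-track tibble
#' @export
read_depth_tsv <- function(path, sample_id, platform = c("TS", "WES")) {
  platform <- match.arg(platform)
  d <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("chrom", "pos", "depth")
  if (!all(need %in% names(d))) {
    stop("depth file must have columns chrom, pos, depth", call. = FALSE)
  }
  if (any(d$pos < 1) || any(d$depth < 0)) {
    stop("depth file: positions must be >= 1 and depths >= 0", call. = FALSE)
  }
  tibble::tibble(sample_id = sample_id, platform = platform,
                 chrom = as.character(d$chrom), pos0 = as.integer(d$pos) - 1L,
                 depth = as.integer(d$depth))
}

#' @param tracks depth-track tibble
#' @rdname read_depth_tsv
#' @export
write_depth_tsv <- function(tracks, path) {
  out <- data.frame(chrom = tracks$chrom, pos = tracks$pos0 + 1L,
                    depth = tracks$depth)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

one_track <- function(tracks) {
  if (nrow(tracks) &&
      (length(unique(tracks$sample_id)) > 1 ||
       length(unique(tracks$platform)) > 1)) {
    stop("expected a single (sample, platform) track; filter first",
         call. = FALSE)
  }
  tracks
}

#' Mean depth of a track over the panel targets
#'
#' Sum of depths over all target bases divided by the total target length;
#' target bases absent from the track count as depth 0, recorded bases
#' outside the targets are ignored.
#'
#' @param track depth-track tibble for one sample and platform
#' @param design a `panel_design`
#' @return mean depth (x-fold)
#' @export
sample_mean_depth <- function(track, design) {
  track <- one_track(track)
  len <- panel_size(design)
  if (len == 0) stop("no target bases", call. = FALSE)
  inside <- positions_in_intervals(track$chrom, track$pos0, design$targets)
  sum(as.numeric(track$depth[inside])) / len
}

#' Percentage of target bases at or above a depth threshold
#'
#' @inheritParams sample_mean_depth
#' @param threshold minimum depth counted as covered (default 10)
#' @return percentage in `[0, 100]`
#' @export
pct_bases_at_threshold <- function(track, design, threshold = 10) {
  stopifnot(threshold >= 0)
  track <- one_track(track)
  len <- panel_size(design)
  if (len == 0) stop("no target bases", call. = FALSE)
  inside <- positions_in_intervals(track$chrom, track$pos0, design$targets)
  covered <- sum(track$depth[inside] >= threshold)
  # target bases absent from the track have depth 0
  if (threshold <= 0) covered <- covered + (len - sum(inside))
  100 * covered / len
}

#' Per-sample coverage summary table
#'
#' One row per (sample, platform): mean target depth and the percentage of
#' target bases covered at `threshold` or deeper.
#'
#' @param tracks depth-track tibble (any number of samples/platforms)
#' @inheritParams pct_bases_at_threshold
#' @return tibble with `sample_id`, `platform`, `mean_depth`,
#'   `pct_at_threshold`
#' @export
coverage_by_sample <- function(tracks, design, threshold = 10) {
  len <- panel_size(design)
  if (len == 0) stop("no target bases", call. = FALSE)
  inside <- positions_in_intervals(tracks$chrom, tracks$pos0, design$targets)
  tracks[inside, ] |>
    dplyr::group_by(sample_id, platform) |>
    dplyr::summarise(
      mean_depth = sum(as.numeric(depth)) / len,
      pct_at_threshold = 100 * (sum(depth >= threshold) +
        if (threshold <= 0) len - dplyr::n() else 0L) / len,
      .groups = "drop")
}

#' Per-gene pooled mean depth for one platform
#'
#' For each panel gene, the mean depth over the gene's (flanked, merged)
#' target bases pooled across every sample of the platform: total depth sum
#' divided by (number of samples x gene target length). Genes with zero
#' target bases are excluded with a warning.
#'
#' @param tracks depth-track tibble
#' @param design a `panel_design` with per-gene provenance
#' @param platform `"TS"` or `"WES"`
#' @return tibble with `gene`, `platform`, `pooled_mean_depth`
#' @export
gene_pooled_depth <- function(tracks, design, platform = c("TS", "WES")) {
  platform <- match.arg(platform)
  tr <- tracks[tracks$platform == platform, , drop = FALSE]
  n_samples <- length(unique(tr$sample_id))
  if (n_samples == 0) stop("no tracks for platform ", platform, call. = FALSE)
  genes <- unique(design$provenance$gene)
  rows <- lapply(genes, function(g) {
    iv <- merge_intervals(design$provenance[design$provenance$gene == g,
                                            c("chrom", "start", "end")])
    len <- sum(iv$end - iv$start)
    if (len == 0) {
      warning("gene ", g, " has zero target bases; excluded", call. = FALSE)
      return(NULL)
    }
    inside <- positions_in_intervals(tr$chrom, tr$pos0, iv)
    tibble::tibble(gene = g, platform = platform,
                   pooled_mean_depth = sum(as.numeric(tr$depth[inside])) /
                     (n_samples * len))
  })
  dplyr::bind_rows(rows)
}

# per-(exon, sample) mean depth for one platform; exon unit is the raw
# (unflanked) exon interval
exon_sample_depth <- function(tracks, design, platform) {
  tr <- tracks[tracks$platform == platform, , drop = FALSE]
  samples <- unique(tr$sample_id)
  ex <- design$exons
  rows <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- tr[tr$sample_id == samples[k], , drop = FALSE]
    means <- numeric(nrow(ex))
    for (cn in unique(ex$chrom)) {
      sel_e <- which(ex$chrom == cn)
      sc <- s[s$chrom == cn, , drop = FALSE]
      sc <- sc[order(sc$pos0), , drop = FALSE]
      cs <- c(0, cumsum(as.numeric(sc$depth)))
      lo <- findInterval(ex$start[sel_e] - 0.5, sc$pos0) + 1L
      hi <- findInterval(ex$end[sel_e] - 0.5, sc$pos0)
      tot <- ifelse(hi >= lo, cs[hi + 1L] - cs[lo], 0)
      means[sel_e] <- tot / (ex$end[sel_e] - ex$start[sel_e])
    }
    rows[[k]] <- tibble::tibble(sample_id = samples[k], platform = platform,
                                gene = ex$gene, exon_id = ex$exon_id,
                                mean_depth = means)
  }
  dplyr::bind_rows(rows)
}

#' Fraction of (exon, sample) units with low mean depth
#'
#' Pooled across all samples of the platform: the fraction of exon-sample
#' units whose mean depth over the raw exon interval is below `threshold`.
#'
#' @inheritParams gene_pooled_depth
#' @param threshold depth below which an exon counts as low-covered
#'   (default 10)
#' @return fraction in `[0, 1]`
#' @export
exon_low_coverage_fraction <- function(tracks, design,
                                       platform = c("TS", "WES"),
                                       threshold = 10) {
  platform <- match.arg(platform)
  es <- exon_sample_depth(tracks, design, platform)
  if (nrow(es) == 0) return(0)
  mean(es$mean_depth < threshold)
}

#' Full coverage summary for a paired-platform experiment
#'
#' Bundles the per-sample table, per-gene pooled depths for both platforms,
#' and the per-platform exon low-coverage fractions.
#'
#' @inheritParams coverage_by_sample
#' @return list with `per_sample`, `per_gene`, `exon_low` (tibble with
#'   `platform`, `fraction`), and `threshold`
#' @export
coverage_summary <- function(tracks, design, threshold = 10) {
  platforms <- intersect(c("TS", "WES"), unique(tracks$platform))
  per_gene <- dplyr::bind_rows(lapply(platforms, function(p)
    gene_pooled_depth(tracks, design, p)))
  exon_low <- tibble::tibble(
    platform = platforms,
    fraction = vapply(platforms, function(p)
      exon_low_coverage_fraction(tracks, design, p, threshold), 0))
  list(per_sample = coverage_by_sample(tracks, design, threshold),
       per_gene = per_gene, exon_low = exon_low, threshold = threshold)
}
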