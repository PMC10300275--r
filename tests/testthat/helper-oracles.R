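# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use brute force / enumeration, not the package's
# own code paths.

# base-set union of intervals as a character set "chrom:pos"
oracle_base_set <- function(intervals) {
  if (nrow(intervals) == 0) return(character(0))
  unique(unlist(lapply(seq_len(nrow(intervals)), function(i)
    paste0(intervals$chrom[i], ":",
           seq.int(intervals$start[i], intervals$end[i] - 1L)))))
}

# apply a variant to a chromosome string; errors if REF disagrees
oracle_apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# exhaustive two-sided signed-rank p-value over all 2^n sign assignments
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# a tiny two-gene design used widely below
tiny_design <- function(flank = 0) {
  g <- tibble::tibble(
    gene = c("G1", "G1", "G2"),
    category = c("iron overload", "iron overload", "lipid metabolism"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 300L, 1000L),
    end = c(200L, 360L, 1100L),
    region_type = "exon")
  build_targets(g, flank = flank)
}

# constant-depth track over every target base of a design
uniform_track <- function(design, depth, sample_id = "S1", platform = "TS") {
  b <- panelval:::target_bases(design)
  tibble::tibble(sample_id = sample_id, platform = platform,
                 chrom = b$chrom, pos0 = b$pos0,
                 depth = as.integer(depth))
}

# minimal valid callset row(s); override any field by name
make_calls <- function(n = 1, ...) {
  out <- tibble::tibble(
    sample_id = rep("S1", n), platform = "TS", chrom = "chr1",
    pos = seq_len(n) + 100L, ref = "C", alt = "T",
    depth = 50L, alt_fraction = 0.5, filter_pass = TRUE,
    rsid = NA_character_, consequence = "missense_variant",
    clinvar_sig = "Not_found", maf_exac_nfe = 0, cadd = 25,
    gene = "G1", gc_pct = 45, repeat_flag = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# random reference chromosome with homopolymer-prone composition
random_reference <- function(len = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(0.3, 0.3, 0.2, 0.2)), collapse = "")
}

# small simulation config for fast property runs; any argument of
# simulation_config() may be overridden
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 4, exons_per_gene = c(2, 3),
         exon_length = c(60, 100), n_samples = 3,
         dropout_rate_ts = 0.02, dropout_rate_wes = 0.08,
         n_background = 5),
    list(...))
  do.call(simulation_config, args)
}
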