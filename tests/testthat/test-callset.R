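test_that("left normalization preserves the edited haplotype and is idempotent", {
  ref <- "TTACCCGAT"
  # deletion of one C from the CCC run, spelled three ways
  spellings <- list(c(4L, "CC", "C"), c(5L, "CC", "C"), c(3L, "ACC", "AC"))
  normed <- lapply(spellings, function(s) {
    v <- make_calls(1, chrom = "chr1", pos = as.integer(s[1]),
                    ref = s[2], alt = s[3])
    left_normalize(v, list(chr1 = ref))
  })
  keys <- vapply(normed, variant_key, "")
  expect_equal(length(unique(keys)), 1)
  # normalized edit produces the same haplotype as the original spelling
  for (i in seq_along(spellings)) {
    s <- spellings[[i]]; n <- normed[[i]]
    expect_equal(oracle_apply_edit(ref, n$pos, n$ref, n$alt),
                 oracle_apply_edit(ref, as.integer(s[1]), s[2], s[3]))
  }
  # idempotence
  twice <- left_normalize(normed[[1]], list(chr1 = ref))
  expect_equal(twice[c("pos", "ref", "alt")], normed[[1]][c("pos", "ref", "alt")])
})

test_that("shared prefix/suffix trimming reduces MNVs to their minimal form", {
  ref <- "AAAAAAAAAGCTAA"  # GCT at positions 10-12
  v <- make_calls(1, chrom = "chr1", pos = 10L, ref = "GCT", alt = "GAT")
  n <- left_normalize(v, list(chr1 = ref))
  expect_equal(n$pos, 11L)
  expect_equal(n$ref, "C")
  expect_equal(n$alt, "A")
  # SNVs are fixed points
  snv <- make_calls(1, chrom = "chr1", pos = 3L, ref = "A", alt = "G")
  expect_equal(left_normalize(snv, list(chr1 = ref)), snv)
})

test_that("normalization errors on a REF that contradicts the reference", {
  v <- make_calls(1, chrom = "chr1", pos = 2L, ref = "GG", alt = "G")
  expect_error(left_normalize(v, list(chr1 = "ATTTT")), "REF mismatch")
})

test_that("random indel respellings converge to one key (haplotype oracle)", {
  seq <- random_reference(300, seed = 123)
  for (rep in 1:25) {
    pos <- sample(20:250, 1)
    if (runif(1) < 0.5) {  # deletion of 1-3 bases
      k <- sample(1:3, 1)
      ref <- substr(seq, pos, pos + k)
      alt <- substr(seq, pos, pos)
    } else {               # insertion of 1-3 random bases
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                                      replace = TRUE), collapse = ""))
    }
    if (ref == alt) next
    v1 <- make_calls(1, chrom = "c", pos = as.integer(pos), ref = ref, alt = alt)
    # respell with an extra shared flanking base on both sides
    v2 <- make_calls(1, chrom = "c", pos = as.integer(pos - 1),
                     ref = paste0(substr(seq, pos - 1, pos - 1), ref,
                                  substr(seq, pos + nchar(ref),
                                         pos + nchar(ref))),
                     alt = paste0(substr(seq, pos - 1, pos - 1), alt,
                                  substr(seq, pos + nchar(ref),
                                         pos + nchar(ref))))
    n1 <- left_normalize(v1, list(c = seq))
    n2 <- left_normalize(v2, list(c = seq))
    expect_equal(variant_key(n1), variant_key(n2))
    expect_equal(oracle_apply_edit(seq, n1$pos, n1$ref, n1$alt),
                 oracle_apply_edit(seq, pos, ref, alt))
  }
})

test_that("normalization agrees with bcftools norm on random indels", {
  skip_if(Sys.which("bcftools") == "", "bcftools not on PATH")
  seq <- random_reference(200, seed = 77)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">c", seq), fa)
  system2("samtools", c("faidx", fa), stdout = FALSE, stderr = FALSE)
  set.seed(5)
  rows <- list()
  for (i in 1:12) {
    pos <- sample(20:150, 1)
    k <- sample(1:3, 1)
    if (runif(1) < 0.5) {
      ref <- substr(seq, pos, pos + k); alt <- substr(seq, pos, pos)
    } else {
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE), collapse = ""))
    }
    if (ref != alt) rows[[length(rows) + 1]] <- c(pos, ref, alt)
  }
  vcf <- file.path(dir, "in.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=c>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               vapply(rows, function(r)
                 sprintf("c\t%s\t.\t%s\t%s\t.\t.\t.", r[1], r[2], r[3]), "")),
             vcf)
  out <- system2("bcftools", c("norm", "-f", fa, vcf),
                 stdout = TRUE, stderr = FALSE)
  out <- out[!startsWith(out, "#")]
  bt <- do.call(rbind, strsplit(out, "\t"))
  calls <- make_calls(length(rows),
                      chrom = "c",
                      pos = as.integer(vapply(rows, `[`, "", 1)),
                      ref = vapply(rows, `[`, "", 2),
                      alt = vapply(rows, `[`, "", 3))
  n <- left_normalize(calls, list(c = seq))
  # bcftools orders its output by position; compare as variant sets
  expect_setequal(paste(n$pos, n$ref, n$alt),
                  paste(as.integer(bt[, 2]), bt[, 4], bt[, 5]))
})

test_that("target restriction keeps exactly the anchored-in-target calls", {
  d <- tiny_design()  # targets chr1:[100,200)+[300,360), chr2:[1000,1100)
  calls <- make_calls(4, chrom = c("chr1", "chr1", "chr2", "chr2"),
                      pos = c(101L, 100L, 1100L, 1101L))
  kept <- restrict_to_targets(calls, d)
  expect_equal(kept$pos, c(101L, 1100L))
  # random positions against brute-force membership
  set.seed(31)
  rnd <- make_calls(60, chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
                    pos = sample(1:1300, 60))
  keep <- paste0(rnd$chrom, ":", rnd$pos - 1) %in% oracle_base_set(d$targets)
  expect_equal(variant_key(restrict_to_targets(rnd, d)),
               variant_key(rnd[keep, ]))
})

test_that("depth and allele-fraction filters honor their boundaries", {
  calls <- make_calls(3, depth = c(9L, 10L, 50L))
  expect_equal(apply_depth_filter(calls)$depth, c(10L, 50L))
  af <- make_calls(3, platform = c("WES", "WES", "TS"),
                   alt_fraction = c(0.19, 0.20, 0.10))
  out <- apply_af_filter(af)
  expect_equal(nrow(out), 2)            # WES 0.19 dropped
  expect_true(0.20 %in% out$alt_fraction)  # WES 0.20 kept
  expect_true("TS" %in% out$platform)      # TS untouched at 0.10
  expect_equal(apply_depth_filter(calls, 5), calls)  # all-pass identity
})

test_that("filters commute and only shrink callsets", {
  set.seed(13)
  d <- tiny_design()
  calls <- make_calls(80,
                      platform = sample(c("TS", "WES"), 80, replace = TRUE),
                      chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                      pos = sample(1:1300, 80),
                      depth = sample(0:40, 80, replace = TRUE),
                      alt_fraction = runif(80))
  orders <- list(
    function(x) restrict_to_targets(apply_af_filter(apply_depth_filter(x)), d),
    function(x) apply_depth_filter(apply_af_filter(restrict_to_targets(x, d))),
    function(x) apply_af_filter(restrict_to_targets(apply_depth_filter(x), d)))
  keys <- lapply(orders, function(f) sort(variant_key(f(calls))))
  expect_equal(keys[[1]], keys[[2]])
  expect_equal(keys[[2]], keys[[3]])
  expect_lte(length(keys[[1]]), nrow(calls))
})

test_that("callset TSV round trip is lossless and validated", {
  calls <- make_calls(3, rsid = c("rs1", NA, "rs3"),
                      maf_exac_nfe = c(0, 0.0301, NA),
                      cadd = c(29.7, NA, 5),
                      repeat_flag = c(TRUE, FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_callset(calls, f)
  back <- read_callset(f)
  expect_equal(back, calls)
  bad <- make_calls(1, maf_exac_nfe = 1.5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_callset(f2), "maf")
  expect_error(read_callset(f, platform = "XX"), "unknown platform")
})

test_that("flat-dialect row with published annotations parses faithfully", {
  row <- make_calls(1, rsid = "rs61733458", clinvar_sig = "Benign",
                    cadd = 29.7, maf_exac_nfe = 0.0301,
                    consequence = "Exonic non-synonymous", gene = "CP")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_callset(row, f)
  back <- read_callset(f, platform = "TS")
  expect_equal(back$clinvar_sig, "Benign")
  expect_equal(back$cadd, 29.7)
  expect_equal(back$maf_exac_nfe, 0.0301)
})

test_that("ClinVar significance strings map onto the closed vocabulary", {
  expect_equal(
    map_clinvar_sig(c("Pathogenic", "Likely pathogenic",
                      "Uncertain significance",
                      "Conflicting interpretations of pathogenicity",
                      "Likely benign", "Benign", "Not_Found", NA)),
    c("Pathogenic", "Likely_pathogenic", "Uncertain", "Conflicting",
      "Likely_benign", "Benign", "Not_found", "Not_found"))
  expect_warning(out <- map_clinvar_sig("??weird??"), "unrecognized")
  expect_equal(out, "Not_found")
})

test_that("VCF records parse, split multi-allelics and map annotations", {
  skip_if_not_installed("VariantAnnotation")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=2000>",
    '##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD">',
    '##INFO=<ID=ExAC_NFE,Number=1,Type=Float,Description="MAF">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA001",
    paste0("chr1\t101\trs111\tC\tT\t50\tPASS\t",
           "CLNSIG=Benign;CADD=29.7;ExAC_NFE=0.0301;",
           "CSQ=missense_variant;GENE=CP\tGT:DP\t0/1:88"),
    paste0("chr1\t202\t.\tG\tA,C\t50\tPASS\t",
           "CLNSIG=Uncertain_significance;CADD=10;ExAC_NFE=0;",
           "CSQ=synonymous_variant;GENE=XX\tGT:DP\t0/1:40")), vcf)
  calls <- read_callset_vcf(vcf, platform = "TS")
  expect_equal(nrow(calls), 3)  # multi-allelic split
  expect_equal(calls$alt, c("T", "A", "C"))
  expect_equal(calls$clinvar_sig[1], "Benign")
  expect_equal(calls$maf_exac_nfe[1], 0.0301)
  expect_equal(calls$depth, c(88L, 40L, 40L))
  expect_equal(calls$rsid[1], "rs111")
  expect_true(all(calls$filter_pass))
})

test_that("GC content window is computed from the reference", {
  seq <- paste(rep(c("G", "C", "A", "T"), each = 25), collapse = "")
  expect_equal(gc_content_pct(list(c1 = seq), "c1", 25, half_window = 10), 100)
  expect_equal(gc_content_pct(list(c1 = seq), "c1", 90, half_window = 5), 0)
  mixed <- gc_content_pct(list(c1 = seq), "c1", 50, half_window = 50)
  expect_gt(mixed, 40); expect_lt(mixed, 60)
})
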