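ts_wes_pair <- function(n_shared, n_ts, n_wes, start = 100L) {
  pos <- start + seq_len(n_shared + n_ts + n_wes)
  shared <- seq_len(n_shared)
  ts_u <- n_shared + seq_len(n_ts)
  wes_u <- n_shared + n_ts + seq_len(n_wes)
  list(
    ts = make_calls(n_shared + n_ts, platform = "TS",
                    pos = pos[c(shared, ts_u)]),
    wes = make_calls(n_shared + n_wes, platform = "WES",
                     pos = pos[c(shared, wes_u)]))
}

test_that("callset comparison partitions keys three ways", {
  p <- ts_wes_pair(5, 0, 0)
  cmp <- compare_callsets(p$ts, p$wes)
  expect_equal(length(cmp$ts_only), 0)
  expect_equal(length(cmp$wes_only), 0)
  expect_equal(length(cmp$shared), 5)

  p <- ts_wes_pair(0, 4, 3)
  cmp <- compare_callsets(p$ts, p$wes)
  expect_equal(length(cmp$shared), 0)
  expect_equal(length(cmp$ts_only), 4)
  expect_equal(length(cmp$wes_only), 3)

  set.seed(23)
  for (rep in 1:20) {
    k <- sample(0:6, 3, replace = TRUE)
    cmp <- with(ts_wes_pair(k[1], k[2], k[3]), compare_callsets(ts, wes))
    expect_equal(length(cmp$shared), k[1])
    # sum rule: the partition covers the union exactly
    expect_equal(length(cmp$shared) + length(cmp$ts_only) +
                   length(cmp$wes_only), nrow(cmp$per_variant))
    expect_equal(nrow(cmp$per_variant), sum(k))
  }
})

test_that("truth assignment follows confirmation labels, shared calls are true", {
  p <- ts_wes_pair(2, 2, 1)
  cmp <- compare_callsets(p$ts, p$wes)
  sanger <- tibble::tibble(key = c(cmp$ts_only, cmp$wes_only),
                           confirmed = c(TRUE, FALSE, TRUE))
  cmp <- assign_truth(cmp, sanger)
  pv <- cmp$per_variant
  expect_equal(pv$truth[pv$in_ts & pv$in_wes],
               rep("true_shared", 2))  # no label needed for dual detection
  expect_equal(sort(pv$truth[pv$in_ts & !pv$in_wes]),
               c("false_unconfirmed", "true_confirmed"))
  expect_equal(pv$truth[!pv$in_ts & pv$in_wes], "true_confirmed")
  # a unique variant without a label is excluded with a warning
  expect_warning(assign_truth(cmp, sanger[-1, ]), "without a confirmation")
})

test_that("detection rate and specificity match direct arithmetic", {
  p <- ts_wes_pair(89, 6, 3)
  cmp <- compare_callsets(p$ts, p$wes)
  sanger <- tibble::tibble(
    key = c(cmp$ts_only, cmp$wes_only),
    confirmed = c(rep(TRUE, 4), FALSE, FALSE, rep(TRUE, 3)))
  cmp <- assign_truth(cmp, sanger)
  expect_equal(detection_rate(cmp, "TS"), 96.9)   # 93/96, half-up
  expect_equal(detection_rate(cmp, "WES"), 95.8)  # 92/96
  expect_equal(specificity(cmp, "TS"), 97.9)      # 93/95
  expect_equal(specificity(cmp, "WES"), 100)
  m <- concordance_metrics(cmp)
  expect_equal(m$counts$total_true, 96)
  expect_equal(m$counts$false_TS, 2)
  expect_equal(m$counts$calls_WES, 92)
  # perfect platform: calls every true variant, no false ones
  p2 <- ts_wes_pair(5, 0, 0)
  cmp2 <- assign_truth(compare_callsets(p2$ts, p2$wes),
                       tibble::tibble(key = character(), confirmed = logical()))
  expect_equal(detection_rate(cmp2, "TS"), 100)
  expect_equal(specificity(cmp2, "TS"), 100)
})

test_that("removing a false call never decreases specificity", {
  set.seed(41)
  for (rep in 1:10) {
    n_s <- sample(3:10, 1); n_t <- sample(1:5, 1)
    p <- ts_wes_pair(n_s, n_t, 1)
    cmp <- compare_callsets(p$ts, p$wes)
    conf <- c(runif(n_t) < 0.5, TRUE)
    sanger <- tibble::tibble(key = c(cmp$ts_only, cmp$wes_only),
                             confirmed = conf)
    cmp <- assign_truth(cmp, sanger)
    s0 <- specificity(cmp, "TS")
    false_keys <- cmp$per_variant$key[
      cmp$per_variant$truth == "false_unconfirmed" & cmp$per_variant$in_ts]
    if (!length(false_keys)) next
    ts2 <- p$ts[variant_key(p$ts) != false_keys[1], ]
    cmp2 <- assign_truth(compare_callsets(ts2, p$wes), sanger)
    expect_gte(specificity(cmp2, "TS"), s0)
  }
})

test_that("three-set summaries round percentages half-up to integers", {
  v <- venn_summary(288, 66, 20)
  expect_equal(unname(v$counts[["total"]]), 374)
  expect_equal(unname(v$pct), c(77, 18, 5))
  v2 <- venn_summary(89, 4, 3)
  expect_equal(unname(v2$pct), c(93, 4, 3))
  v0 <- venn_summary(0, 0, 0)
  expect_equal(unname(v0$counts[["total"]]), 0)
  expect_equal(unname(v0$pct), c(0, 0, 0))
})

test_that("discrepancy reasons follow the fixed cascade", {
  d <- tiny_design()
  # TS-unique call at chr1:101 carried by S1; WES-unique at chr2:1001
  ts <- make_calls(2, pos = c(101L, 102L), gc_pct = c(55, 75))
  wes <- make_calls(1, platform = "WES", chrom = "chr2", pos = 1001L)
  cmp <- compare_callsets(ts, wes)
  base <- uniform_track(d, 50, platform = "TS")
  # WES track: depth 0 at chr1:101 locus, deep elsewhere
  wes_tr <- uniform_track(d, 50, platform = "WES")
  wes_tr$depth[wes_tr$chrom == "chr1" & wes_tr$pos0 == 100L] <- 0L
  tracks <- dplyr::bind_rows(base, wes_tr)
  sanger <- tibble::tibble(key = c(variant_key(ts), variant_key(wes)),
                           confirmed = c(TRUE, FALSE, TRUE))
  cmp <- assign_truth(cmp, sanger)

  # (1) insufficient coverage in the non-calling platform wins first
  cmp1 <- assign_discrepancy_reason(cmp, tracks)
  pv <- cmp1$per_variant
  expect_equal(pv$reason[pv$key == variant_key(ts)[1]],
               "insufficient_coverage_other_platform")
  # (2) filter-failed record in the other platform, depth adequate
  raw <- dplyr::bind_rows(ts, wes,
                          make_calls(1, platform = "WES", pos = 102L,
                                     gc_pct = 75, filter_pass = FALSE))
  cmp2 <- assign_discrepancy_reason(cmp, tracks, raw_calls = raw)
  pv2 <- cmp2$per_variant
  expect_equal(pv2$reason[pv2$key == variant_key(ts)[2]],
               "pipeline_filter_fail")
  # (3) without that record, the unconfirmed GC-rich call is a misalignment FP
  expect_equal(pv$reason[pv$key == variant_key(ts)[2]],
               "false_positive_misalignment")
  # (4) confirmed, covered, no failed record: unexplained
  expect_equal(pv$reason[pv$key == variant_key(wes)],
               "unexplained")
  # TS depth 15 at a WES-unique locus: insufficient only under a stricter
  # configured reason threshold
  tracks15 <- tracks
  tracks15$depth[tracks15$platform == "TS" & tracks15$chrom == "chr2" &
                   tracks15$pos0 == 1000L] <- 15L
  r10 <- assign_discrepancy_reason(cmp, tracks15)$per_variant
  r20 <- assign_discrepancy_reason(cmp, tracks15,
                                   reason_depth_threshold = 20)$per_variant
  k <- variant_key(wes)
  expect_equal(r10$reason[r10$key == k], "unexplained")
  expect_equal(r20$reason[r20$key == k],
               "insufficient_coverage_other_platform")
})
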