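---
title: "Benchmarking a targeted gene panel against exome sequencing with panelval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking a targeted gene panel against exome sequencing with panelval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

## The problem

Diagnostic laboratories that adopt a custom targeted sequencing panel (TS)
for a disease area — here, hereditary chronic liver disease — need to show
that the panel performs at least as well as whole-exome sequencing (WES)
on the genes it covers. The comparison has three parts: coverage (is the
panel deeper and more uniform over its target regions?), variant-level
concordance (do the two assays call the same variants, and when they do
not, why?), and summary performance (detection rate and specificity
against a truth standard built from dual detection and orthogonal Sanger
confirmation). `panelval` implements this validation analysis as a
reusable, fully testable pipeline.

## Panel model

A panel is a set of genes, each a list of coding exons plus optional UTR
and promoter regions, in one of six clinical categories. Targets are the
coding exons expanded by a symmetric flank (default 25 bp, the common
capture-design convention for catching splice-region variants), unioned
with the extra regions, and merged per chromosome. Internally all
intervals are BED-convention 0-based half-open; VCF-style 1-based
coordinates appear only at the variant and depth-file boundaries, so both
file formats round-trip bit-exactly. Book-ended intervals merge, which
makes the total target length equal the size of the base-set union — the
denominator of every coverage statistic.

Two open choices were resolved as follows. Flanks are applied to exons
only, not to UTR/promoter regions: the extra regions are included because
specific pathogenic variants fall inside them, so they are taken as
annotated. And the real 82-gene diagnostic panel is not bundled; the
package ships a six-gene toy fixture (`toy_panel()`, one gene per
category) and every analysis accepts a user-supplied gene table.

## Coverage statistics

Per-sample mean depth is the sum of per-base depths over all target bases
divided by the total target length; bases missing from a depth track
count as zero. "Percent of targets covered at 10x" counts bases with
depth >= 10: the threshold is read as *at least* tenfold, consistent with
the 10x calling cutoff, so a base at exactly 10x is covered. Per-gene
depth pools all samples of a platform over the gene's merged flanked
intervals. The exon low-coverage fraction counts (exon, sample) units
whose mean depth over the raw exon interval is below threshold, pooled
across samples — the unit is exon-by-sample rather than exon alone so a
dropout in one library is visible even when other samples cover the exon
well.

Platform comparisons use the paired Wilcoxon signed-rank test on per-gene
pooled depths (pairing by gene; zero differences dropped before ranking,
the classic convention, with the exact null distribution for up to 25
informative pairs and the continuity-corrected normal approximation
beyond) and the uncorrected Pearson chi-squared test for the 2x2
low-coverage exon table. Both delegate to the standard `stats`
implementations; the package's tests verify the signed-rank p-value
against exhaustive enumeration of all 2^n sign assignments at small n.

## Variant handling

Callsets enter as a flat TSV dialect or as VCF (via VariantAnnotation;
multi-allelic records are split before anything else). Indels are
left-normalized against the reference — shared trailing bases trimmed
with leftward extension through repeat runs, then shared leading bases
trimmed — yielding the unique left-most minimal representation, the same
convention as `bcftools norm` (the test suite cross-checks against
bcftools on random indels). Variants match across platforms by the
canonical key `chrom:pos:ref:alt` after normalization; rsIDs are carried
as metadata only, since identifier annotation differs between pipelines.

Three filters reproduce the upstream calling rules: a depth cutoff
(default 10x, boundary kept), the WES-only allele-fraction cutoff
(variants in < 20% of reads discarded; exactly 20% is kept; the TS caller
applies no such rule, so the filter is scoped to WES), and restriction to
the panel targets, judged by the normalized record's anchor base. The
filters commute, which the suite checks by property test.

## The high-functional-impact cascade

A variant is triaged as high functional impact (HFI) only if its
consequence is exonic non-synonymous (missense, nonsense, frameshift),
UTR, or splice-site, and then by the first matching criterion:

* **A** — ClinVar Pathogenic or Likely pathogenic;
* **B** — allele frequency (ExAC non-Finnish European) below 0.005,
  with an absent or zero frequency counting as rare;
* **C** — frequency in the closed band [0.005, 0.05] with CADD
  strictly above 20.

Two details follow the published classification rather than intuition:
ClinVar Benign or Likely-benign labels do *not* exclude a variant from B
or C ("VUS" is read operationally as "not Pathogenic/Likely-pathogenic"),
and "Conflicting interpretations" routes to the same non-pathogenic
branch. Boundary conventions are literal: B is strict `<`, C's band is
closed, CADD is strict `>`. The cascade is monotone in both frequency
(downward) and CADD (upward), which the suite verifies by property test.
The same thresholds apply to exonic, UTR and splice variants alike; the
published discrepancy tables contain only exonic rows, so they cannot
discriminate, and a single rule is the simpler model.

## Concordance, truth, and discrepancy reasons

Callsets are partitioned by key into shared, TS-only and WES-only sets.
Matching is at key level across the cohort: a key called by both
platforms is shared. Variants detected by both platforms are accepted as
true without orthogonal testing — that is how the published metrics are
defined, and it is the only reading that makes a 96-variant truth
universe from 89 shared plus 7 confirmed unique calls. Platform-unique
variants need a Sanger label: confirmed ones are true, unconfirmed ones
false; unlabeled ones are excluded from metrics with a warning.

Detection rate is true variants called by a platform over all true
variants; specificity is true calls over all calls of the platform. Both
are reported half-up to one decimal; three-set summaries round
percentages half-up to integers, matching the conventional reporting
precision.

Each platform-unique variant receives one reason from a fixed cascade:
(1) the non-calling platform's depth at the locus (in the carrier
samples) below a threshold — insufficient coverage; (2) otherwise a
record at the key that failed the non-calling platform's pipeline filter
(e.g. a VQSR tranche) — pipeline filtering; (3) otherwise, for
unconfirmed calls in GC-rich (>= 70%) or repeat-flagged sequence —
misalignment false positive; (4) otherwise unexplained. The coverage
threshold of step (1) defaults to the 10x calling cutoff but is
configurable (`reason_depth_threshold`): published discrepancy tables
label loci at 10-15x as insufficiently covered, implying a stricter
internal notion of "sufficient" than the calling cutoff, and the package
does not guess that value — with the default 10 such rows come out
`unexplained`, with 20 they reproduce the published labels. The GC
threshold of 70% is the smallest rule consistent with the published
false-positive rows (73.5% and 75% GC).

## The synthetic-data generator

`simulation_config()` defines the study conditions the generator
emulates; its defaults are fixed at the validation cohort's structure and
are not tuning knobs:

* 19 samples, paired platforms over a simulated multi-gene panel;
* per-sample TS mean depth lognormal with mean 300x and sd 190x (the
  cohort's heavy spread), WES truncated-normal with mean 102x and sd 7x;
  per-base depth negative-binomial (size 8) around the sample mean —
  the paper-style summaries state only means and ranges, so the
  two-parameter family is the package's own choice, chosen because it
  reproduces a wide TS spread with realistic per-base noise;
* dropout segments (depth sampled from 0-9) planted exon-wise to cover
  3% (TS) and 13% (WES) of target bases, WES dropouts preferring
  GC-rich-flagged exons, so ~97% and ~87% of bases are covered at 10x;
  the non-dropout mean is inflated correspondingly so the realized
  track mean stays at the drawn sample mean;
* a planted callset of 89 shared true, 4 TS-only true (half invisible
  to WES through forced sub-10x depth, half through a filter-failed WES
  record), 3 WES-only true (sub-10x TS depth), and 2 TS false positives
  carrying misalignment-compatible annotation and "not confirmed"
  labels — the realized decomposition of the validation cohort — plus
  60 shared synonymous background variants;
* annotations drawn from criterion-conditional ranges so every planted
  HFI verdict is decidable by construction (e.g. criterion C: MAF
  uniform in the band, CADD uniform above 20).

All variants are SNVs at distinct exonic positions; indel normalization
is exercised on its own fixtures instead. Depth at every calling
platform's locus is forced to at least 30x so planted calls always
survive the filters, making planted-count recovery exact by design — the
suite verifies exact (TP, FP, FN) recovery over 100 random
configurations. One seed drives a single generator stream through all
stages; identical configurations are byte-identical.

What the generator does not emulate: real capture-efficiency profiles,
GC-dependent depth *gradients* (dropout is planted, not emergent),
sequencing error, mapping ambiguity, indel calling, or annotation noise.
Passing recovery tests therefore demonstrates that the *analysis* is
correct and self-consistent, not that any particular assay would achieve
these numbers on patients.

## Numerical choices and degenerate inputs

Rounding is half-up (not banker's) at the stated precisions. Empty
designs raise "no target bases"; empty callsets produce a zero-count
report rather than an error; an all-zero difference vector gives a
signed-rank p of 1 with a warning; a chi-squared table with a zero
marginal is rejected as degenerate. Flanks floor at position 0. Unknown
chromosomes in containment queries return `FALSE`, not an error.
Unrecognized ClinVar strings map to `Not_found` with a warning.

## Problem sizes

The shipped tests run the full default scenario (19 samples, a 12-gene
panel of 4-8 exons of 120-220 bp, ~16,000 target bases) once, and the
100-configuration recovery property on reduced panels (4 genes, 3
samples) to keep a full suite run around a minute; the pipeline itself
is linear in target bases x samples.

## Limitations

Metrics are computed over deduplicated variant keys, not genotypes;
zygosity is out of scope, as are the upstream callers, annotation
engines and confirmation chemistry, which enter only as depths, filter
flags and labels. The published raw counts that depend on the original
reads (total variant universe, per-gene p-values) are emulation targets
for the simulator, not quantities the package claims to reproduce from
first principles.
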