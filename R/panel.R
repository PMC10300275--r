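#' The six panel gene categories
#'
#' The panel groups its disease genes into six clinical categories (iron
#' overload, lipid metabolism, cholestatic diseases, storage diseases,
#' specific hereditary chronic liver diseases, susceptibility to liver
#' diseases). Gene-model inputs must use one of these values.
#'
#' @return character vector of the six category names
#' @export
panel_categories <- function() {
  c("iron overload", "lipid metabolism", "cholestatic diseases",
    "storage diseases", "specific hereditary CLD",
    "susceptibility to liver diseases")
}

#' Read a gene-model table
#'
#' Tab-separated with header columns `gene`, `category`, `chrom`, `start`,
#' `end`, `region_type` (`exon`, `utr` or `promoter`); coordinates 0-based
#' half-open. One row per exon or extra region.
#'
#' @param path file path
#' @return tibble of gene models suitable for [build_targets()]
#' @export
read_gene_models <- function(path) {
  g <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("gene", "category", "chrom", "start", "end", "region_type")
  miss <- setdiff(need, names(g))
  if (length(miss)) {
    stop("gene-model file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_gene_models(g)
  g
}

validate_gene_models <- function(genes) {
  bad_cat <- setdiff(unique(genes$category), panel_categories())
  if (length(bad_cat)) {
    stop("unknown gene category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(genes$region_type), c("exon", "utr", "promoter"))
  if (length(bad_type)) {
    stop("unknown region_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  validate_intervals(genes, context = genes$gene)
  invisible(genes)
}

#' Build a panel design from gene models
#'
#' Each coding exon is expanded by `flank` bases on both sides (floored at
#' position 0), unioned with any extra regions (UTRs, promoters, taken
#' as-is), and merged per chromosome into the panel's target intervals.
#' Per-gene provenance is retained so per-gene coverage statistics remain
#' possible after merging.
#'
#' @param genes gene-model tibble (`gene`, `category`, `chrom`, `start`,
#'   `end`, `region_type`); see [read_gene_models()]
#' @param flank non-negative flanking width in bp added to each exon
#'   (default 25)
#' @return a `panel_design` object: list with `genes` (the input), `targets`
#'   (merged interval tibble), `provenance` (per-gene merged intervals),
#'   `exons` (raw exon intervals with `exon_id`), and `flank`
#' @export
#' @examples
#' g <- tibble::tibble(gene = "HFE", category = "iron overload",
#'                     chrom = "chr6", start = 1000, end = 1200,
#'                     region_type = "exon")
#' build_targets(g, flank = 25)$targets
build_targets <- function(genes, flank = 25) {
  stopifnot(is.numeric(flank), length(flank) == 1, flank >= 0)
  flank <- as.integer(flank)
  if (nrow(genes) == 0) {
    empty <- tibble::tibble(chrom = character(), start = integer(), end = integer())
    return(structure(
      list(genes = genes, targets = empty,
           provenance = tibble::tibble(gene = character(), chrom = character(),
                                       start = integer(), end = integer()),
           exons = tibble::tibble(gene = character(), exon_id = character(),
                                  chrom = character(), start = integer(),
                                  end = integer()),
           flank = flank),
      class = "panel_design"))
  }
  validate_gene_models(genes)

  flanked <- genes
  is_exon <- flanked$region_type == "exon"
  flanked$start[is_exon] <- pmax(0L, as.integer(flanked$start[is_exon]) - flank)
  flanked$end[is_exon] <- as.integer(flanked$end[is_exon]) + flank

  prov <- dplyr::bind_rows(lapply(split(flanked, flanked$gene), function(d) {
    m <- merge_intervals(d[, c("chrom", "start", "end")])
    m$gene <- d$gene[1]
    m
  }))
  prov <- dplyr::select(prov, gene, chrom, start, end)

  exons <- genes[is_exon, c("gene", "chrom", "start", "end")]
  exons <- dplyr::arrange(exons, gene, chrom, start)
  exons$exon_id <- paste0(exons$gene, "_e",
                          stats::ave(seq_len(nrow(exons)), exons$gene,
                                     FUN = seq_along))
  exons <- dplyr::select(exons, gene, exon_id, chrom, start, end)

  structure(
    list(genes = genes,
         targets = merge_intervals(flanked[, c("chrom", "start", "end")]),
         provenance = tibble::as_tibble(prov),
         exons = tibble::as_tibble(exons),
         flank = flank),
    class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("<panel_design> %d genes, %d target intervals, %d bp (flank %d)\n",
              length(unique(x$genes$gene)), nrow(x$targets),
              panel_size(x), x$flank))
  invisible(x)
}

#' Total target length of a panel design in bases
#' @param design a `panel_design`
#' @return integer number of bases in the merged target set
#' @export
panel_size <- function(design) {
  if (nrow(design$targets) == 0) return(0L)
  sum(design$targets$end - design$targets$start)
}

#' Test whether 1-based positions fall inside panel targets
#'
#' The 1-based position `pos` covers target base `pos - 1` in the package's
#' internal 0-based half-open convention; the conversion happens here.
#' Unknown chromosomes yield `FALSE`, not an error.
#'
#' @param design a `panel_design`
#' @param chrom chromosome names (recycled against `pos`)
#' @param pos 1-based positions (VCF convention)
#' @return logical vector
#' @export
panel_contains <- function(design, chrom, pos) {
  stopifnot(all(pos >= 1))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  positions_in_intervals(chrom, pos - 1L, design$targets)
}
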