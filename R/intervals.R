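#' Genomic intervals
#'
#' Intervals are represented throughout the package as tibbles with columns
#' `chrom` (character), `start` and `end`, in BED convention: 0-based,
#' half-open `[start, end)`. 1-based coordinates appear only at the variant
#' (VCF-style) and depth-file boundaries, where the conversion happens.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors; `0 <= start < end`
#' @return a tibble with columns `chrom`, `start`, `end`
#' @export
#' @examples
#' genomic_intervals("chr1", 975, 1225)
genomic_intervals <- function(chrom, start, end) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end   = as.integer(end)
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, context = NULL) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("interval table must have columns chrom, start, end", call. = FALSE)
  }
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) | is.na(x$start) |
                 is.na(x$end) | x$start < 0 | x$end <= x$start)
  if (length(bad)) {
    i <- bad[1]
    who <- if (!is.null(context)) paste0(context[i], ": ") else ""
    stop(sprintf("invalid interval %s%s:[%s,%s)",
                 who, x$chrom[i], x$start[i], x$end[i]), call. = FALSE)
  }
  invisible(x)
}

#' Merge genomic intervals into a disjoint sorted set
#'
#' Overlapping and book-ended intervals (`[a,b)` + `[b,c)`) are merged, so the
#' total length of the output equals the size of the base-set union of the
#' input. Output is sorted by chromosome then start.
#'
#' @param intervals interval tibble (see [genomic_intervals()])
#' @return interval tibble, sorted, pairwise disjoint and non-adjacent
#' @export
#' @examples
#' merge_intervals(genomic_intervals(c("chr1", "chr1"), c(0, 10), c(10, 20)))
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  validate_intervals(intervals)
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    # 0-based half-open -> 1-based closed for IRanges; reduce() merges
    # overlapping and adjacent ranges
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    tibble::tibble(chrom = d$chrom[1],
                   start = IRanges::start(r) - 1L,
                   end   = IRanges::end(r))
  })
  dplyr::arrange(dplyr::bind_rows(out[order(names(out))]), chrom, start)
}

total_interval_length <- function(intervals) {
  if (nrow(intervals) == 0) return(0L)
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

# Vectorized membership of 0-based positions in a merged, sorted interval set.
# `targets` must already be merged (disjoint, sorted per chrom).
positions_in_intervals <- function(chrom, pos0, targets) {
  out <- logical(length(pos0))
  if (nrow(targets) == 0 || length(pos0) == 0) return(out)
  for (cn in unique(chrom)) {
    t <- targets[targets$chrom == cn, , drop = FALSE]
    sel <- which(chrom == cn)
    if (nrow(t) == 0) next
    idx <- findInterval(pos0[sel], t$start)
    out[sel] <- idx >= 1 & pos0[sel] < t$end[pmax(idx, 1L)]
  }
  out
}

#' Read and write BED3 interval files
#'
#' Plain BED3 (chrom, start, end; 0-based half-open, tab-separated, no
#' header). A write-then-read round trip preserves the merged base set
#' exactly.
#'
#' @param path file path
#' @return `read_bed()`: an interval tibble
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) {
      stop(sprintf("BED parse error at line %d: expected >= 3 fields", i),
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(p[2]))
    e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop(sprintf("BED parse error at line %d: invalid interval [%s,%s)",
                   i, p[2], p[3]), call. = FALSE)
    }
  }
  tibble::tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = vapply(parts, function(p) as.integer(p[2]), 1L),
    end   = vapply(parts, function(p) as.integer(p[3]), 1L)
  )
}

#' @param x an interval tibble or a `panel_design` (its merged targets are
#'   written)
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "panel_design")) x <- x$targets
  validate_intervals(x)
  writeLines(sprintf("%s\t%d\t%d", x$chrom, x$start, x$end), path)
  invisible(path)
}
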