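#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired values (e.g. per-gene pooled
#' depths under the two platforms). Zero differences are dropped before
#' ranking (classic Wilcoxon convention, not Pratt). The exact distribution
#' is used for n <= 25 effective pairs when there are no ties in the
#' absolute differences; otherwise the normal approximation with continuity
#' correction.
#'
#' @param x,y paired numeric vectors of equal length
#' @return two-sided p-value
#' @export
#' @examples
#' paired_signed_rank(c(5, 7, 9, 11), c(4, 6, 8, 10))
paired_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(1.0)
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  res <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", mu = 0,
                exact = exact, correct = TRUE))
  unname(res$p.value)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-squared with one
#' degree of freedom, as used to compare low-coverage exon proportions
#' between platforms.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`
#' @return two-sided p-value
#' @export
#' @examples
#' two_by_two_chi_squared(10, 90, 20, 180)  # proportional table -> p = 1
two_by_two_chi_squared <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a zero marginal", call. = FALSE)
  }
  unname(suppressWarnings(chisq.test(m, correct = FALSE))$p.value)
}
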