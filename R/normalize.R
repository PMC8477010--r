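#' Median-of-ratios library size factors
#'
#' Estimates one positive scaling factor per sample by the median-of-ratios
#' method: each sample's counts are divided by a pseudo-reference sample
#' (the per-gene geometric mean across samples, using only genes with no
#' zero count), and the factor is the median of those ratios. Factors are
#' rescaled to have geometric mean 1, so normalized counts stay on the
#' scale of the raw data.
#'
#' @param x A [count_matrix()] or a bare counts matrix.
#' @return Named numeric vector of per-sample size factors
#'   (geometric mean 1).
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' size_factors(m)  # ratio exactly 2
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)  # genes with any zero are excluded
  if (!any(use))
    .stopf(paste0("no gene has all-positive counts; pre-filter very sparse ",
                  "genes or provide deeper libraries before normalization"))
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo[use])))
  sf / exp(mean(log(sf)))
}

#' Normalized counts
#'
#' Raw counts divided by their size factors.
#'
#' @param x A [count_matrix()] or matrix.
#' @param factors Output of [size_factors()]; computed if missing.
#' @return Matrix of normalized counts.
#' @export
normalized_counts <- function(x, factors = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(factors)) factors <- size_factors(counts)
  sweep(counts, 2, factors, "/")
}
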