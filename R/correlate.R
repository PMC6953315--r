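#' Sample-by-sample expression correlation
#'
#' The data-exploration stage: genes whose summed count across samples is
#' <= `minTotalCount` are removed, the rest are CPM-transformed and
#' log2(x+1)-transformed, and Pearson correlation is computed between
#' sample columns.  Samples are ordered by average-linkage hierarchical
#' clustering of Euclidean distances between correlation-row vectors (the
#' ordering used for correlation heatmaps).
#'
#' @param counts count matrix, genes x samples (>= 2 samples).
#' @param minTotalCount genes with row sum <= this are dropped (default 10).
#' @return list with `r` (symmetric correlation matrix, unit diagonal),
#'   `ordering` (integer permutation of samples) and `nGenesUsed`.
#' @export
sampleCorrelation <- function(counts, minTotalCount = 10) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  keep <- rowSums(counts) > minTotalCount
  if (sum(keep) < 2) stop("fewer than two genes survive the count filter")
  x <- log2(cpmValues(counts[keep, , drop = FALSE]) + 1)
  r <- stats::cor(x, method = "pearson")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  hc <- stats::hclust(stats::dist(r, method = "euclidean"),
                      method = "average")
  list(r = r, ordering = hc$order, nGenesUsed = sum(keep))
}
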