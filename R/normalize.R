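#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors.  For each sample a weighted
#' trimmed mean of gene-wise log2 expression ratios against a reference
#' sample is computed: genes with a zero count in either sample are
#' excluded, the most extreme `logratioTrim` fraction of M values and
#' `sumTrim` fraction of A values are trimmed from each tail, and the
#' remaining M values are averaged with inverse asymptotic-variance
#' (delta-method binomial) weights.  The reference is the sample whose
#' upper-quartile CPM is closest to the mean upper quartile.  Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts non-negative count matrix, genes x samples (>= 2 samples).
#' @param logratioTrim fraction trimmed from each tail of M (default 0.30).
#' @param sumTrim fraction trimmed from each tail of A (default 0.05).
#' @return named numeric vector of positive factors, geometric mean 1.
#' @examples
#' m <- matrix(c(10, 20, 5, 10, 40, 4), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' tmmFactors(m)
#' @export
tmmFactors <- function(counts, logratioTrim = 0.30, sumTrim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    bad <- colnames(counts)[libs <= 0]
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  cpm <- t(t(counts) / libs) * 1e6
  uq <- apply(cpm, 2, .quantile75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    .tmmPair(counts[, i], counts[, ref], libs[i], libs[ref],
             logratioTrim, sumTrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Type-7 upper quartile without quantile()'s name formatting.
.quantile75 <- function(x) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Stable (first-occurrence) ranks.
.rankFirst <- function(x) {
  r <- integer(length(x))
  r[order(x, seq_along(x))] <- seq_along(x)
  r
}

# One-sample-vs-reference trimmed weighted mean of M values.
.tmmPair <- function(obs, ref, nO, nR, logratioTrim, sumTrim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1;      hiA <- n + 1 - loA
  rM <- .rankFirst(M)
  rA <- .rankFirst(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel) || sum(1 / v[sel]) == 0) return(1)
  fq <- 2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
  if (!is.finite(fq) || fq <= 0) 1 else fq
}

#' Counts per million
#'
#' `entry = count / (librarySize * factor) * 1e6`.  With `factors = NULL`
#' raw library sizes are used; with TMM factors the result is TMM-scaled
#' CPM.  The returned matrix carries a `"scale"` attribute (`"cpm"` or
#' `"tmm-cpm"`).
#'
#' @param counts count matrix, genes x samples.
#' @param factors optional named normalization factors (see [tmmFactors()]).
#' @param libSizes optional library sizes; default `colSums(counts)`.
#' @return numeric matrix with attribute `scale`.
#' @export
cpmValues <- function(counts, factors = NULL, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(libSizes <= 0)) stop("library sizes must be positive")
  eff <- libSizes
  scale <- "cpm"
  if (!is.null(factors)) {
    if (!is.null(names(factors)) && !is.null(colnames(counts)))
      factors <- factors[colnames(counts)]
    eff <- libSizes * factors
    scale <- "tmm-cpm"
  }
  out <- t(t(counts) / eff) * 1e6
  attr(out, "scale") <- scale
  out
}

#' Transform TMM-CPM to centred log2 expression
#'
#' `x -> log2(x + 1)`, then each gene (row) is centred on its mean — the
#' scale used by the published per-gene expression tables.  Requires input
#' on the `"tmm-cpm"` scale; the result carries scale `"log2p1-centered"`.
#'
#' @param expr matrix from [cpmValues()] with scale `"tmm-cpm"`.
#' @return numeric matrix with row means 0 and attribute
#'   `scale = "log2p1-centered"`.
#' @export
transformExpression <- function(expr) {
  if (!identical(attr(expr, "scale"), "tmm-cpm"))
    stop("input must be on the tmm-cpm scale")
  out <- log2(expr + 1)
  out <- out - rowMeans(out)
  attr(out, "scale") <- "log2p1-centered"
  out
}

#' Write / read a numeric gene x sample matrix as TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @return `writeMatrixTsv` the path invisibly; `readMatrixTsv` a matrix.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
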