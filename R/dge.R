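#' Specify one pairwise OTU-vs-OTU comparison
#'
#' Collects the samples on each side and flags which EOD features the two
#' OTUs contrast.  A feature is contrasted when it is applicable to both
#' OTUs (polarity only applies to triphasic OTUs) and their phenotypes
#' differ.
#'
#' @param design a [StudyDesign-class].
#' @param otuA,otuB distinct OTU labels from the design.
#' @return list with `otuA`, `otuB`, `samplesA`, `samplesB` and `contrasts`
#'   (named logical vector over features).
#' @export
comparisonSpec <- function(design, otuA, otuB) {
  stopifnot(otuA != otuB, all(c(otuA, otuB) %in% otuLabels(design)))
  contr <- vapply(eodFeatures(design), function(f) {
    a <- phenotypeOf(design, otuA, f)
    b <- phenotypeOf(design, otuB, f)
    !is.na(a) && !is.na(b) && a != b
  }, logical(1))
  list(otuA = otuA, otuB = otuB,
       samplesA = samplesOfOtu(design, otuA),
       samplesB = samplesOfOtu(design, otuB),
       contrasts = contr)
}

#' Filter to expressed genes for one comparison
#'
#' Keeps genes whose CPM (computed with raw library sizes, pre-TMM) exceeds
#' `minCpm` in at least `minSamples` of the comparison's samples.
#'
#' @param counts count matrix covering the comparison's samples.
#' @param spec a [comparisonSpec()].
#' @param minCpm CPM threshold (strict `>`; default 1).
#' @param minSamples minimum number of samples above threshold (default 2).
#' @return character vector of gene identifiers.
#' @export
filterExpressed <- function(counts, spec, minCpm = 1, minSamples = 2) {
  smp <- c(spec$samplesA, spec$samplesB)
  stopifnot(all(smp %in% colnames(counts)))
  sub <- as.matrix(counts)[, smp, drop = FALSE]
  cpm <- cpmValues(sub)
  keep <- rowSums(cpm > minCpm) >= minSamples
  if (!any(keep))
    stop("no expressed genes for comparison ", spec$otuA, " vs ", spec$otuB)
  rownames(sub)[keep]
}

# Scale counts to the geometric-mean effective library size, rounding
# half-to-even, so the exact test's conditioning on totals is valid.
.equalizeCounts <- function(counts, effLibs) {
  lStar <- exp(mean(log(effLibs)))
  pseudo <- round(t(t(counts) * (lStar / effLibs)))
  storage.mode(pseudo) <- "double"
  pseudo
}

# Conditional (on per-gene group total) NB log-likelihood for one group of
# equalized counts; vectorized over genes, `phi` scalar or per-gene.
.condLogLik <- function(y, phi) {
  n <- ncol(y)
  if (n < 2) return(numeric(nrow(y)))
  r <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) - lgamma(z + n * r) + lgamma(n * r)
}

#' Common qCML dispersion for a two-group comparison
#'
#' Maximizes the summed conditional (on per-group totals) negative-binomial
#' log-likelihood over genes, on counts equalized to the geometric-mean
#' effective library size.  The search is bracketed on \[1e-6, 10\] with
#' tolerance 1e-6; if the likelihood is monotone decreasing the lower
#' bound is returned.
#'
#' @param counts count matrix (typically restricted to expressed genes).
#' @param spec a [comparisonSpec()].
#' @param effLibs named effective library sizes for the comparison's
#'   samples; default raw library sizes of `counts`.
#' @return scalar dispersion estimate.
#' @export
estimateCommonDispersion <- function(counts, spec,
                                     effLibs = NULL) {
  smp <- c(spec$samplesA, spec$samplesB)
  counts <- as.matrix(counts)[, smp, drop = FALSE]
  if (is.null(effLibs)) effLibs <- colSums(counts)
  pseudo <- .equalizeCounts(counts, effLibs[smp])
  yA <- pseudo[, spec$samplesA, drop = FALSE]
  yB <- pseudo[, spec$samplesB, drop = FALSE]
  obj <- function(phi) sum(.condLogLik(yA, phi)) + sum(.condLogLik(yB, phi))
  opt <- stats::optimize(obj, interval = c(1e-6, 10), maximum = TRUE,
                         tol = 1e-6)
  if (obj(1e-6) >= opt$objective) 1e-6 else opt$maximum
}

# Vectorized golden-section maximization over log-dispersion.
.goldenMaxPhi <- function(f, lo = 1e-6, hi = 10, iters = 60L, nGenes) {
  gr <- (sqrt(5) - 1) / 2
  a <- rep(log(lo), nGenes); b <- rep(log(hi), nGenes)
  for (i in seq_len(iters)) {
    c1 <- b - gr * (b - a)
    d1 <- a + gr * (b - a)
    go_right <- f(exp(c1)) < f(exp(d1))
    a[go_right] <- c1[go_right]
    b[!go_right] <- d1[!go_right]
  }
  phi <- exp((a + b) / 2)
  # pin to the lower bound when the likelihood is decreasing throughout
  atLo <- f(rep(lo, nGenes)) >= f(phi)
  phi[atLo] <- lo
  phi
}

#' Tagwise (per-gene) dispersion by weighted conditional likelihood
#'
#' Each gene's conditional log-likelihood is augmented with
#' `priorDf / residDf` times the shared likelihood (the average conditional
#' log-likelihood over all genes, interpolated from a 200-point
#' log-dispersion grid), shrinking per-gene estimates toward the common
#' value; `priorDf = 0` gives unshrunk per-gene maxima and
#' `priorDf -> Inf` recovers the common estimate for every gene.
#'
#' @inheritParams estimateCommonDispersion
#' @param common common dispersion (used only to seed the grid range).
#' @param priorDf prior degrees of freedom (default 10).
#' @return named per-gene dispersion vector.
#' @export
estimateTagwiseDispersion <- function(counts, spec, common, priorDf = 10,
                                      effLibs = NULL) {
  smp <- c(spec$samplesA, spec$samplesB)
  counts <- as.matrix(counts)[, smp, drop = FALSE]
  if (is.null(effLibs)) effLibs <- colSums(counts)
  pseudo <- .equalizeCounts(counts, effLibs[smp])
  yA <- pseudo[, spec$samplesA, drop = FALSE]
  yB <- pseudo[, spec$samplesB, drop = FALSE]
  G <- nrow(pseudo)
  perGene <- function(phi) .condLogLik(yA, phi) + .condLogLik(yB, phi)

  residDf <- max(1L, length(spec$samplesA) + length(spec$samplesB) - 2L)
  priorN <- priorDf / residDf
  if (is.finite(priorN) && priorN > 0) {
    grid <- exp(seq(log(1e-6), log(10), length.out = 200))
    sharedVals <- vapply(grid, function(p) mean(perGene(p)), numeric(1))
    shared <- stats::splinefun(log(grid), sharedVals, method = "natural")
    obj <- function(phi) perGene(phi) + priorN * shared(log(phi))
  } else if (is.infinite(priorN)) {
    return(setNames(rep(common, G), rownames(pseudo)))
  } else {
    obj <- perGene
  }
  phi <- .goldenMaxPhi(obj, nGenes = G)
  setNames(phi, rownames(pseudo))
}

# Two-sided conditional NB exact p-value for one gene: probability mass of
# all splits of the total no more likely than the observed one
# (minimum-likelihood method).  `phi = 0` is the Poisson limit (conditional
# binomial).
.exactNbPval <- function(zA, zB, nA, nB, phi) {
  z <- zA + zB
  if (z == 0) return(1)
  a <- 0:z
  if (phi < 1e-10) {
    logp <- stats::dbinom(a, z, nA / (nA + nB), log = TRUE)
  } else {
    r <- 1 / phi
    rA <- nA * r; rB <- nB * r
    logp <- lgamma(a + rA) - lgamma(a + 1) - lgamma(rA) +
            lgamma(z - a + rB) - lgamma(z - a + 1) - lgamma(rB)
    m <- max(logp)
    logp <- logp - (m + log(sum(exp(logp - m))))
  }
  pObs <- logp[zA + 1]
  min(1, sum(exp(logp[logp <= pObs + 1e-10])))
}

#' Negative-binomial exact test for one pairwise comparison
#'
#' Counts are equalized to a common (geometric-mean) effective library
#' size; conditional on each gene's total, the two-sided p-value sums the
#' probabilities of all splits between the groups no more likely than the
#' observed one under the negative binomial with the gene's dispersion.
#' log2 fold changes come from TMM-CPM group means with a small prior
#' count; positive `logFC` means up-regulated in `otuA`.
#'
#' @param counts count matrix restricted to the expressed genes of the
#'   comparison (see [filterExpressed()]).
#' @param spec a [comparisonSpec()].
#' @param dispersions per-gene dispersion vector (recycled if scalar).
#' @param effLibs named effective library sizes (raw x TMM); default raw
#'   library sizes of `counts`.
#' @param priorCount prior count for fold-change stabilization, expressed
#'   in counts at the geometric-mean library size (default 0.125).
#' @return A [DGEResult-class].
#' @export
exactTest <- function(counts, spec, dispersions, effLibs = NULL,
                      priorCount = 0.125) {
  smp <- c(spec$samplesA, spec$samplesB)
  counts <- as.matrix(counts)[, smp, drop = FALSE]
  if (is.null(effLibs)) effLibs <- colSums(counts)
  effLibs <- effLibs[smp]
  disp <- rep_len(dispersions, nrow(counts))
  pseudo <- .equalizeCounts(counts, effLibs)
  zA <- rowSums(pseudo[, spec$samplesA, drop = FALSE])
  zB <- rowSums(pseudo[, spec$samplesB, drop = FALSE])
  nA <- length(spec$samplesA); nB <- length(spec$samplesB)
  p <- vapply(seq_len(nrow(counts)), function(i)
    .exactNbPval(zA[i], zB[i], nA, nB, disp[i]), numeric(1))

  cpm <- cpmValues(counts, libSizes = effLibs)
  meanA <- rowMeans(cpm[, spec$samplesA, drop = FALSE])
  meanB <- rowMeans(cpm[, spec$samplesB, drop = FALSE])
  priorCpm <- priorCount * 1e6 / exp(mean(log(effLibs)))
  logFC <- log2((meanA + priorCpm) / (meanB + priorCpm))
  logCPM <- log2(rowMeans(cpm) + priorCpm)

  tab <- data.frame(gene = rownames(counts), logFC = logFC, logCPM = logCPM,
                    PValue = p, FDR = bhAdjust(p),
                    meanCpmA = meanA, meanCpmB = meanB,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- cbind(tab, as.data.frame(counts))
  new("DGEResult", table = tab, otuA = spec$otuA, otuB = spec$otuB,
      samplesA = spec$samplesA, samplesB = spec$samplesB,
      commonDispersion = if (length(dispersions) == 1) dispersions else NA_real_,
      dispersion = setNames(disp, rownames(counts)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NaN` is rejected.
#' @return adjusted p-values (q-values), same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(is.nan(p))) stop("NaN p-values are not allowed")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at the study thresholds
#'
#' Strict inequalities: `|logFC| > minAbsLog2fc` (default 2, i.e. a 4-fold
#' expression difference) and `FDR < maxFdr` (default 0.001).  Direction
#' follows the sign convention of the result table: positive `logFC` is up
#' in `otuA`.
#'
#' @param result a [DGEResult-class].
#' @param minAbsLog2fc minimum absolute log2 fold change (strict).
#' @param maxFdr maximum FDR (strict).
#' @return data.frame with `gene`, `direction` (`"up_in_<otu>"`), `upOtu`,
#'   `logFC`, `FDR`.
#' @export
callDegs <- function(result, minAbsLog2fc = 2, maxFdr = 0.001) {
  tab <- result@table
  hit <- which(abs(tab$logFC) > minAbsLog2fc & tab$FDR < maxFdr)
  up <- ifelse(tab$logFC[hit] > 0, result@otuA, result@otuB)
  up <- as.character(up)
  data.frame(gene = tab$gene[hit],
             direction = if (length(up)) paste0("up_in_", up) else character(0),
             upOtu = up,
             logFC = tab$logFC[hit],
             FDR = tab$FDR[hit],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' MA-plot table for one comparison
#'
#' @param result a [DGEResult-class].
#' @param flagFdr genes with `FDR < flagFdr` are flagged significant
#'   (default 0.05, independent of the DEG-calling threshold).
#' @return data.frame with `gene`, `A` (mean log2 CPM), `logFC`,
#'   `significant`.
#' @export
maTable <- function(result, flagFdr = 0.05) {
  tab <- result@table
  data.frame(gene = tab$gene, A = tab$logCPM, logFC = tab$logFC,
             significant = tab$FDR < flagFdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run one full pairwise comparison on an EodExperiment
#'
#' Applies the expression filter, computes TMM factors on the filtered
#' comparison submatrix, estimates common and tagwise dispersions, and runs
#' the exact test.
#'
#' @param x an [EodExperiment-class].
#' @param otuA,otuB OTU labels.
#' @param minCpm,minSamples see [filterExpressed()].
#' @param priorDf see [estimateTagwiseDispersion()].
#' @param priorCount see [exactTest()].
#' @return A [DGEResult-class].
#' @export
runComparison <- function(x, otuA, otuB, minCpm = 1, minSamples = 2,
                          priorDf = 10, priorCount = 0.125) {
  design <- studyDesign(x)
  spec <- comparisonSpec(design, otuA, otuB)
  counts <- countMatrix(x)
  smp <- c(spec$samplesA, spec$samplesB)
  genes <- filterExpressed(counts, spec, minCpm, minSamples)
  sub <- counts[genes, smp, drop = FALSE]
  effLibs <- colSums(counts[, smp, drop = FALSE]) * tmmFactors(sub)
  common <- estimateCommonDispersion(sub, spec, effLibs)
  tagwise <- estimateTagwiseDispersion(sub, spec, common, priorDf, effLibs)
  res <- exactTest(sub, spec, tagwise, effLibs, priorCount)
  res@commonDispersion <- common
  res
}

#' @rdname DGEResult-accessors
#' @name DGEResult-accessors
#' @title Accessors for DGEResult
#' @param x a [DGEResult-class].
NULL

#' @rdname DGEResult-accessors
#' @export
setMethod("resultTable", "DGEResult", function(x) x@table)

#' @rdname DGEResult-accessors
#' @export
setMethod("comparedOtus", "DGEResult", function(x) c(x@otuA, x@otuB))

setMethod("show", "DGEResult", function(object) {
  cat("DGEResult:", object@otuA, "vs", object@otuB, "-",
      nrow(object@table), "genes tested\n")
  cat("common dispersion:", format(object@commonDispersion, digits = 4), "\n")
  n <- nrow(callDegs(object))
  cat("DEGs at |logFC| > 2, FDR < 0.001:", n, "\n")
})
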