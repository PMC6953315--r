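#' Set A: union of DEGs over all pairwise comparisons
#'
#' @param degCalls list of data.frames from [callDegs()] (one per
#'   comparison).
#' @return sorted, deduplicated character vector of gene identifiers.
#' @export
buildSetA <- function(degCalls) {
  sort(unique(unlist(lapply(degCalls, function(d) d$gene),
                     use.names = FALSE)))
}

#' Select the informative comparison for each EOD feature
#'
#' A comparison is eligible for a feature when its two OTUs contrast that
#' feature and no other applicable feature.  Among eligible comparisons
#' (minus explicit exclusions) the pair with the smallest phylogenetic
#' distance is selected; ties break lexicographically on the OTU pair.
#'
#' @param design a [StudyDesign-class].
#' @param distance symmetric OTU x OTU numeric matrix, positive
#'   off-diagonal.
#' @param exclusions list of length-2 character vectors naming OTU pairs to
#'   exclude (order-insensitive).
#' @return data.frame with one row per feature: `feature`, `otuA`, `otuB`,
#'   `distance`.
#' @export
selectInformativeComparisons <- function(design,
                                         distance = defaultOtuDistances(),
                                         exclusions = list()) {
  otus <- otuLabels(design)
  stopifnot(all(otus %in% rownames(distance)),
            isTRUE(all.equal(distance, t(distance))))
  pairs <- utils::combn(sort(otus), 2, simplify = FALSE)
  exKey <- vapply(exclusions, function(e) paste(sort(e), collapse = "|"),
                  character(1))
  out <- lapply(eodFeatures(design), function(f) {
    elig <- Filter(function(p) {
      spec <- comparisonSpec(design, p[1], p[2])
      spec$contrasts[[f]] && sum(spec$contrasts) == 1 &&
        !(paste(sort(p), collapse = "|") %in% exKey)
    }, pairs)
    if (!length(elig))
      stop("no eligible informative comparison for feature: ", f)
    d <- vapply(elig, function(p) distance[p[1], p[2]], numeric(1))
    key <- vapply(elig, paste, character(1), collapse = "|")
    best <- elig[[order(d, key)[1]]]
    data.frame(feature = f, otuA = best[1], otuB = best[2],
               distance = min(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.setKey <- function(feature, phenotype) paste(feature, phenotype, sep = "|")

# Every (feature, phenotype) key of a design, in feature order.
.allSetKeys <- function(design) {
  unlist(lapply(eodFeatures(design), function(f)
    .setKey(f, sort(names(phenotypeGroups(design, f))))), use.names = FALSE)
}

#' Set A': up-regulated genes of the informative comparisons, keyed by
#' phenotype
#'
#' For each feature, the DEGs of its informative comparison are split by
#' direction and relabeled to the phenotype that the up-regulated OTU bears
#' for that feature.
#'
#' @param degCalls named list of [callDegs()] data.frames; names are
#'   `"<otuA>|<otuB>"` (sorted pair).
#' @param informativeMap output of [selectInformativeComparisons()].
#' @param design a [StudyDesign-class].
#' @return named list, `"<feature>|<phenotype>"` -> sorted gene vector.
#' @export
buildSetAPrime <- function(degCalls, informativeMap, design) {
  out <- list()
  for (i in seq_len(nrow(informativeMap))) {
    f <- informativeMap$feature[i]
    pair <- c(informativeMap$otuA[i], informativeMap$otuB[i])
    key <- paste(sort(pair), collapse = "|")
    if (!key %in% names(degCalls))
      stop("missing DEG calls for informative comparison ", key)
    calls <- degCalls[[key]]
    for (o in pair) {
      ph <- phenotypeOf(design, o, f)
      if (is.na(ph))
        stop("OTU ", o, " has no phenotype for feature ", f)
      out[[.setKey(f, ph)]] <- sort(calls$gene[calls$upOtu == o])
    }
  }
  out[order(names(out))]
}

#' Set B: phenotype-consistency filter on Set A
#'
#' For each feature, samples are grouped by phenotype (polarity groups
#' contain only samples of triphasic OTUs).  A Set A gene is assigned to
#' the higher-mean phenotype iff, on linear TMM-CPM, (1) the pseudocounted
#' ratio of group means exceeds `foldThreshold` and (2) the difference in
#' means exceeds both within-group standard deviations (sample sd, n-1
#' denominator).  All inequalities are strict.
#'
#' @param expr matrix from [cpmValues()] on the `"tmm-cpm"` scale, all
#'   samples.
#' @param design a [StudyDesign-class].
#' @param setAGenes Set A gene identifiers (only these are considered).
#' @param foldThreshold minimum fold difference in group means (default 4).
#' @param pseudocount added to both means before the ratio (default 1).
#' @return named list, `"<feature>|<phenotype>"` -> sorted gene vector.
#' @export
buildSetB <- function(expr, design, setAGenes, foldThreshold = 4,
                      pseudocount = 1) {
  if (!identical(attr(expr, "scale"), "tmm-cpm"))
    stop("expr must be on the tmm-cpm scale")
  out <- list()
  for (f in eodFeatures(design)) {
    grp <- phenotypeGroups(design, f)
    if (length(grp) != 2)
      stop("feature ", f, " does not have exactly two phenotypes")
    if (any(lengths(grp) < 2))
      stop("phenotype group with < 2 samples for feature ", f)
    ph <- sort(names(grp))
    sub <- expr[setAGenes, , drop = FALSE]
    m1 <- rowMeans(sub[, grp[[ph[1]]], drop = FALSE])
    m2 <- rowMeans(sub[, grp[[ph[2]]], drop = FALSE])
    s1 <- apply(sub[, grp[[ph[1]]], drop = FALSE], 1, stats::sd)
    s2 <- apply(sub[, grp[[ph[2]]], drop = FALSE], 1, stats::sd)
    hi <- ifelse(m1 >= m2, ph[1], ph[2])
    mHi <- pmax(m1, m2); mLo <- pmin(m1, m2)
    pass <- (mHi + pseudocount) / (mLo + pseudocount) > foldThreshold &
      (mHi - mLo) > s1 & (mHi - mLo) > s2
    for (p in ph)
      out[[.setKey(f, p)]] <- sort(setAGenes[pass & hi == p])
  }
  out[order(names(out))]
}

#' Set C: per-key intersection of Set A' and Set B
#'
#' @param setAPrime,setB identically keyed lists of gene vectors.
#' @return named list, same keys, sorted intersections.
#' @export
buildSetC <- function(setAPrime, setB) {
  stopifnot(identical(sort(names(setAPrime)), sort(names(setB))))
  out <- lapply(names(setAPrime), function(k)
    sort(intersect(setAPrime[[k]], setB[[k]])))
  names(out) <- names(setAPrime)
  out[order(names(out))]
}

#' Build the full gene-set family for an experiment
#'
#' Runs all pairwise comparisons, forms Set A, selects the informative
#' comparisons, and derives Sets A', B and C.
#'
#' @param x an [EodExperiment-class].
#' @param distance OTU distance matrix (default [defaultOtuDistances()]
#'   when the design's OTUs match the packaged labels).
#' @param exclusions comparisons excluded from informative-map selection.
#' @param minCpm,minSamples,priorDf,priorCount passed to [runComparison()].
#' @param minAbsLog2fc,maxFdr passed to [callDegs()].
#' @param foldThreshold,pseudocount passed to [buildSetB()].
#' @param comparisons optional precomputed named list of [DGEResult-class]
#'   objects keyed `"<otuA>|<otuB>"` (sorted); computed if `NULL`.
#' @return list with `family` ([GeneSetFamily-class]), `comparisons`
#'   (named list of [DGEResult-class]), `degCalls` and `universes` (per-
#'   comparison expressed-gene lists).
#' @export
buildGeneSetFamily <- function(x, distance = defaultOtuDistances(),
                               exclusions = list(c("PMAG1", "PMAG2")),
                               minCpm = 1, minSamples = 2, priorDf = 10,
                               priorCount = 0.125, minAbsLog2fc = 2,
                               maxFdr = 0.001, foldThreshold = 4,
                               pseudocount = 1, comparisons = NULL) {
  design <- studyDesign(x)
  pairs <- utils::combn(sort(otuLabels(design)), 2, simplify = FALSE)
  if (is.null(comparisons)) {
    comparisons <- lapply(pairs, function(p)
      runComparison(x, p[1], p[2], minCpm, minSamples, priorDf, priorCount))
    names(comparisons) <- vapply(pairs, paste, character(1), collapse = "|")
  }
  degCalls <- lapply(comparisons, callDegs, minAbsLog2fc = minAbsLog2fc,
                     maxFdr = maxFdr)
  universes <- lapply(comparisons, function(r) sort(r@table$gene))

  sA <- buildSetA(degCalls)
  imap <- selectInformativeComparisons(design, distance, exclusions)
  sAp <- buildSetAPrime(degCalls, imap, design)
  expr <- cpmValues(countMatrix(x), tmmFactors(countMatrix(x)))
  sB <- buildSetB(expr, design, sA, foldThreshold, pseudocount)
  sC <- buildSetC(sAp, sB)
  fam <- new("GeneSetFamily", setA = sA, setAPrime = sAp, setB = sB,
             setC = sC, informativeMap = imap)
  list(family = fam, comparisons = comparisons, degCalls = degCalls,
       universes = universes)
}

#' @name GeneSetFamily-accessors
#' @title Accessors for GeneSetFamily
#' @param x a [GeneSetFamily-class].
#' @param feature,phenotype optional key selectors; with both `NULL` the
#'   full keyed list is returned.
NULL

.pickKey <- function(lst, feature, phenotype) {
  if (is.null(feature)) return(lst)
  if (is.null(phenotype)) {
    lst[startsWith(names(lst), paste0(feature, "|"))]
  } else {
    lst[[.setKey(feature, phenotype)]]
  }
}

#' @rdname GeneSetFamily-accessors
#' @export
setMethod("setA", "GeneSetFamily", function(x) x@setA)

#' @rdname GeneSetFamily-accessors
#' @export
setMethod("setAPrime", "GeneSetFamily", function(x, feature = NULL,
                                                 phenotype = NULL)
  .pickKey(x@setAPrime, feature, phenotype))

#' @rdname GeneSetFamily-accessors
#' @export
setMethod("setB", "GeneSetFamily", function(x, feature = NULL,
                                            phenotype = NULL)
  .pickKey(x@setB, feature, phenotype))

#' @rdname GeneSetFamily-accessors
#' @export
setMethod("setC", "GeneSetFamily", function(x, feature = NULL,
                                            phenotype = NULL)
  .pickKey(x@setC, feature, phenotype))

setMethod("show", "GeneSetFamily", function(object) {
  cat("GeneSetFamily: |Set A| =", length(object@setA), "\n")
  for (k in names(object@setC))
    cat(sprintf("  %-22s A'=%4d B=%4d C=%4d\n", k,
                length(object@setAPrime[[k]]), length(object@setB[[k]]),
                length(object@setC[[k]])))
})
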