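#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' StudyDesign: samples, OTUs and per-feature phenotypes
#'
#' Maps each sample to an operational taxonomic unit (OTU) and each OTU to a
#' phenotype for every electric-organ-discharge (EOD) waveform feature
#' (`duration`, `complexity`, `polarity`).  The polarity phenotype only
#' applies to OTUs with triphasic (penetration-bearing) electrocytes; for
#' biphasic OTUs it is `NA`.
#'
#' @slot samples character vector of sample identifiers.
#' @slot otu named character vector, sample -> OTU label.
#' @slot phenotypes data.frame with one row per OTU (rownames = OTU labels)
#'   and one column per feature; entries are phenotype labels or `NA`.
#' @slot features ordered character vector of feature names.
#'
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(
    samples    = "character",
    otu        = "character",
    phenotypes = "data.frame",
    features   = "character"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (anyDuplicated(object@samples))
    msg <- c(msg, "duplicated sample identifiers")
  if (!identical(sort(names(object@otu)), sort(object@samples)))
    msg <- c(msg, "every sample must map to exactly one OTU")
  otus <- rownames(object@phenotypes)
  if (!all(object@otu %in% otus))
    msg <- c(msg, "sample mapped to an OTU absent from the phenotype table")
  if (!all(otus %in% object@otu))
    msg <- c(msg, "every OTU needs at least one sample")
  if (!all(object@features %in% colnames(object@phenotypes)))
    msg <- c(msg, "phenotype table lacks a column for some feature")
  # polarity is defined exactly for triphasic-complexity OTUs
  if (all(c("complexity", "polarity") %in% object@features)) {
    tri <- object@phenotypes[otus, "complexity"] == "triphasic"
    pol <- !is.na(object@phenotypes[otus, "polarity"])
    if (!identical(unname(tri), unname(pol)))
      msg <- c(msg, "polarity must be defined exactly for triphasic OTUs")
  }
  if (length(msg)) msg else TRUE
})

#' EodExperiment: counts plus study design
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `counts` assay holds
#' non-negative integer gene x sample expression counts, whose `colData`
#' carries the `otu` assignment, and whose metadata stores the full
#' [StudyDesign] (and, for simulated data, the truth table).
#'
#' @exportClass EodExperiment
setClass("EodExperiment", contains = "SummarizedExperiment")

setValidity("EodExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "counts must be integers")
  }
  if (!"otu" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain an 'otu' column")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique gene identifiers (rownames) required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique sample identifiers (colnames) required")
  if (length(msg)) msg else TRUE
})

#' DGEResult: one pairwise OTU-vs-OTU exact-test comparison
#'
#' @slot table data.frame with one row per tested gene: `gene`, `logFC`
#'   (positive = up in `otuA`), `logCPM`, `PValue`, `FDR`, `meanCpmA`,
#'   `meanCpmB`, followed by raw counts per sample.
#' @slot otuA,otuB the two OTU labels.
#' @slot samplesA,samplesB sample identifiers on each side.
#' @slot commonDispersion qCML common dispersion used.
#' @slot dispersion named per-gene (tagwise) dispersions.
#'
#' @exportClass DGEResult
setClass("DGEResult",
  representation(
    table            = "data.frame",
    otuA             = "character",
    otuB             = "character",
    samplesA         = "character",
    samplesB         = "character",
    commonDispersion = "numeric",
    dispersion       = "numeric"
  )
)

setValidity("DGEResult", function(object) {
  msg <- character()
  need <- c("gene", "logFC", "logCPM", "PValue", "FDR")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
  else {
    p <- object@table$PValue
    q <- object@table$FDR
    if (any(p < 0 | p > 1)) msg <- c(msg, "p-values outside [0, 1]")
    if (any(q + 1e-12 < p)) msg <- c(msg, "FDR must be >= p componentwise")
  }
  if (identical(object@otuA, object@otuB)) msg <- c(msg, "otuA == otuB")
  if (length(msg)) msg else TRUE
})

#' GeneSetFamily: the nested Set A / A' / B / C gene lists
#'
#' Set A is the non-redundant union of DEGs over all pairwise comparisons;
#' Set A' holds the up-regulated genes of the three informative comparisons
#' keyed by (feature, phenotype); Set B is the phenotype-consistency filter
#' applied to Set A; Set C is the per-key intersection of A' and B.
#' Keys are `"<feature>|<phenotype>"`.
#'
#' @exportClass GeneSetFamily
setClass("GeneSetFamily",
  representation(
    setA           = "character",
    setAPrime      = "list",
    setB           = "list",
    setC           = "list",
    informativeMap = "data.frame"
  )
)

setValidity("GeneSetFamily", function(object) {
  msg <- character()
  keys <- names(object@setAPrime)
  if (!identical(keys, names(object@setB)) || !identical(keys, names(object@setC)))
    msg <- c(msg, "setAPrime, setB, setC must share identical keys")
  else {
    for (k in keys) {
      want <- sort(intersect(object@setAPrime[[k]], object@setB[[k]]))
      if (!identical(sort(object@setC[[k]]), want))
        msg <- c(msg, sprintf("setC[%s] != setAPrime[%s] intersect setB[%s]", k, k, k))
      if (!all(object@setAPrime[[k]] %in% object@setA))
        msg <- c(msg, sprintf("setAPrime[%s] not contained in setA", k))
    }
    feats <- sub("\\|.*$", "", keys)
    for (f in unique(feats)) {
      kk <- keys[feats == f]
      if (length(kk) == 2 &&
          length(intersect(object@setAPrime[[kk[1]]], object@setAPrime[[kk[2]]])))
        msg <- c(msg, sprintf("phenotype lists within feature %s overlap", f))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GODag: a Gene Ontology directed acyclic graph
#'
#' @slot terms data.frame with columns `id`, `name`, `domain` (BP/CC/MF).
#' @slot parents named list, term id -> character vector of parent ids
#'   (is_a and, optionally, part_of edges; empty for roots).
#'
#' @exportClass GODag
setClass("GODag",
  representation(terms = "data.frame", parents = "list")
)

setValidity("GODag", function(object) {
  msg <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated term ids")
  if (!identical(sort(names(object@parents)), sort(ids)))
    msg <- c(msg, "parents list must be keyed by every term id")
  else {
    allp <- unlist(object@parents, use.names = FALSE)
    if (!all(allp %in% ids)) msg <- c(msg, "parent edge to unknown term")
    if (is.null(.topoOrder(object@parents))) msg <- c(msg, "graph is cyclic")
  }
  if (!all(object@terms$domain %in% c("BP", "CC", "MF")))
    msg <- c(msg, "domain must be one of BP, CC, MF")
  if (length(msg)) msg else TRUE
})

# Kahn topological order on child->parents edges; NULL if cyclic.
# Returned order lists children before their parents (leaves first).
.topoOrder <- function(parents) {
  ids <- names(parents)
  nchild <- setNames(integer(length(ids)), ids)
  for (p in unlist(parents, use.names = FALSE)) nchild[p] <- nchild[p] + 1L
  queue <- ids[nchild == 0L]
  out <- character(0)
  while (length(queue)) {
    # lexicographic tie-break for determinism
    queue <- sort(queue)
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (p in parents[[v]]) {
      nchild[p] <- nchild[p] - 1L
      if (nchild[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(ids)) NULL else out
}
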