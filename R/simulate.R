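#' Construct an EodExperiment from counts and a design
#'
#' @param counts non-negative integer matrix, genes x samples; dimnames
#'   required.
#' @param design a [StudyDesign-class] covering the count columns.
#' @param truth optional truth table (`data.frame`) for simulated data.
#' @return An [EodExperiment-class].
#' @export
EodExperiment <- function(counts, design, truth = NULL) {
  stopifnot(identical(colnames(counts), sampleIds(design)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      otu = otuOf(design, colnames(counts)),
      row.names = colnames(counts))
  )
  obj <- new("EodExperiment", se)
  metadata(obj)$design <- design
  if (!is.null(truth)) metadata(obj)$truth <- truth
  obj
}

#' @name EodExperiment-accessors
#' @title Accessors for EodExperiment
#' @param x an [EodExperiment-class].
NULL

#' @rdname EodExperiment-accessors
#' @export
setMethod("studyDesign", "EodExperiment", function(x) metadata(x)$design)

#' @rdname EodExperiment-accessors
#' @export
setMethod("truthTable", "EodExperiment", function(x) metadata(x)$truth)

#' Count assay of an EodExperiment
#' @param x an [EodExperiment-class].
#' @return integer matrix genes x samples.
#' @export
countMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

setMethod("show", "EodExperiment", function(object) {
  cat("EodExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  tab <- table(SummarizedExperiment::colData(object)$otu)
  cat("OTUs:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  if (!is.null(metadata(object)$truth)) {
    tt <- table(metadata(object)$truth$class)
    cat("truth:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  }
})

#' Simulation parameters for synthetic electric-organ count data
#'
#' Defaults emulate the packaged study design at desk scale: ~4000 genes,
#' baseline expression log2-CPM uniform on \[3, 9\] (CPM 8-512, a realistic
#' range for a filtered expressed-gene universe), NB dispersion 0.1,
#' library sizes 200k-500k, 50 planted genes per (feature, phenotype) at
#' 8-fold, and 100 OTU-specific confounder genes per OTU at 4-fold.
#'
#' @param nGenes total number of genes.
#' @param baselineLog2CpmRange length-2 numeric, uniform range of baseline
#'   log2 CPM.
#' @param dispersion scalar NB dispersion (variance = mu + dispersion*mu^2),
#'   or a vector recycled over genes.
#' @param librarySizeRange length-2 integer range for per-sample library
#'   sizes (drawn uniformly).
#' @param nFeatureGenes planted genes per (feature, phenotype) pair.
#' @param featureEffectFold fold change (>= 1) applied to all samples whose
#'   OTU bears the planted up-phenotype.
#' @param nOtuGenes total planted OTU-specific genes, split as evenly as
#'   possible across OTUs (default twice the feature-linked class size).
#' @param otuEffectFold fold change (>= 1) applied to the planted OTU's
#'   samples.
#' @return A named list of validated parameters.
#' @export
simulationParams <- function(nGenes = 4000,
                             baselineLog2CpmRange = c(3, 9),
                             dispersion = 0.1,
                             librarySizeRange = c(200000L, 500000L),
                             nFeatureGenes = 50,
                             featureEffectFold = 8,
                             nOtuGenes = 100,
                             otuEffectFold = 4) {
  stopifnot(nGenes >= 1, featureEffectFold >= 1, otuEffectFold >= 1,
            all(dispersion >= 0), length(baselineLog2CpmRange) == 2,
            length(librarySizeRange) == 2, all(librarySizeRange > 0),
            nFeatureGenes >= 0, nOtuGenes >= 0)
  list(nGenes = nGenes,
       baselineLog2CpmRange = baselineLog2CpmRange,
       dispersion = dispersion,
       librarySizeRange = as.integer(librarySizeRange),
       nFeatureGenes = nFeatureGenes,
       featureEffectFold = featureEffectFold,
       nOtuGenes = nOtuGenes,
       otuEffectFold = otuEffectFold)
}

#' Simulate a count matrix with planted phenotype-linked and OTU-specific
#' genes
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `baselineCPM/1e6 * librarySize * fold`, where `fold` multiplies the
#' baseline for (i) samples whose OTU bears the planted up-phenotype of a
#' feature-linked gene, or (ii) samples of the planted OTU for an
#' OTU-specific confounder gene.  Null genes therefore have identical
#' expected CPM in every sample.  Planted classes are disjoint; class sizes
#' follow `params`.  Deterministic given `seed`.
#'
#' @param design a [StudyDesign-class].
#' @param params see [simulationParams()].
#' @param seed integer seed.
#' @return An [EodExperiment-class]; `truthTable()` returns a data.frame
#'   with columns `gene`, `class` (`null`/`feature`/`otu`), `feature`,
#'   `phenotype`, `otu`.
#' @export
simulateCounts <- function(design, params = simulationParams(), seed = 1L) {
  samples <- sampleIds(design)
  feats <- eodFeatures(design)
  keys <- list()
  for (f in feats) {
    grp <- phenotypeGroups(design, f)
    if (params$nFeatureGenes > 0 && any(lengths(grp) < 2))
      stop("phenotype group with < 2 samples for planted feature: ", f)
    for (p in sort(names(grp))) keys[[length(keys) + 1L]] <- c(f, p)
  }
  otus <- sort(otuLabels(design))
  perOtu <- rep(params$nOtuGenes %/% length(otus), length(otus))
  extra <- params$nOtuGenes %% length(otus)
  if (extra > 0) perOtu[seq_len(extra)] <- perOtu[seq_len(extra)] + 1L
  names(perOtu) <- otus

  nPlanted <- length(keys) * params$nFeatureGenes + params$nOtuGenes
  if (nPlanted > params$nGenes)
    stop("more planted genes than nGenes")

  old <- .Random.seed.exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  g <- params$nGenes
  genes <- sprintf("gene%05d", seq_len(g))
  truth <- data.frame(gene = genes, class = "null",
                      feature = NA_character_, phenotype = NA_character_,
                      otu = NA_character_, stringsAsFactors = FALSE)
  idx <- 0L
  foldMat <- matrix(1, g, length(samples), dimnames = list(genes, samples))
  for (k in keys) {
    if (params$nFeatureGenes == 0) break
    rows <- idx + seq_len(params$nFeatureGenes)
    idx <- idx + params$nFeatureGenes
    truth$class[rows] <- "feature"
    truth$feature[rows] <- k[1]
    truth$phenotype[rows] <- k[2]
    up <- phenotypeGroups(design, k[1])[[k[2]]]
    foldMat[rows, up] <- params$featureEffectFold
  }
  for (o in otus) {
    if (perOtu[[o]] == 0) next
    rows <- idx + seq_len(perOtu[[o]])
    idx <- idx + perOtu[[o]]
    truth$class[rows] <- "otu"
    truth$otu[rows] <- o
    foldMat[rows, samplesOfOtu(design, o)] <- params$otuEffectFold
  }

  baseCpm <- 2^stats::runif(g, params$baselineLog2CpmRange[1],
                            params$baselineLog2CpmRange[2])
  libs <- round(stats::runif(length(samples), params$librarySizeRange[1],
                             params$librarySizeRange[2]))
  mu <- (baseCpm / 1e6) %o% libs * foldMat
  disp <- rep_len(params$dispersion, g)
  counts <- matrix(0L, g, length(samples), dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    m <- mu[, j]
    poisson <- disp < 1e-12
    cj <- numeric(g)
    if (any(poisson)) cj[poisson] <- stats::rpois(sum(poisson), m[poisson])
    if (any(!poisson))
      cj[!poisson] <- stats::rnbinom(sum(!poisson), mu = m[!poisson],
                                     size = 1 / disp[!poisson])
    counts[, j] <- as.integer(cj)
  }
  EodExperiment(counts, design, truth)
}

# Save/restore the caller's RNG state so simulation seeds stay local.
.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
}

#' Simulate a GO DAG and gene annotations
#'
#' Builds a rooted is_a DAG per ontology domain (terms pick 1-2 parents
#' among shallower terms, which guarantees acyclicity) and annotates genes
#' at a background rate, with optional planted terms preferentially
#' annotating chosen gene classes.  Direct annotations are returned; use
#' [propagateAnnotations()] for the ancestor closure.
#'
#' @param genes character vector of gene identifiers.
#' @param nTerms number of non-root terms (split over `domains`).
#' @param dagDepth maximum term depth below a domain root.
#' @param annotationRate background probability that a gene is directly
#'   annotated to a given term.
#' @param plantedTermMap named list: planted term id -> character vector of
#'   genes it preferentially annotates.  Term ids must follow the pattern
#'   `GO:81xxxxx` (they are created if not otherwise generated).
#' @param plantedRate annotation probability for planted (term, gene) pairs.
#' @param domains ontology domains to generate.
#' @param seed integer seed.
#' @return list with `dag` ([GODag-class]) and `annotations` (named list,
#'   gene -> direct term ids).
#' @export
simulateGO <- function(genes, nTerms = 60, dagDepth = 4,
                       annotationRate = 0.05, plantedTermMap = list(),
                       plantedRate = 0.5, domains = "BP", seed = 1L) {
  stopifnot(dagDepth >= 1, nTerms >= 1)
  old <- .Random.seed.exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  roots <- setNames(sprintf("GO:800000%d", seq_along(domains)), domains)
  ids <- character(0); nm <- character(0); dom <- character(0)
  parents <- list(); depth <- integer(0)
  for (d in domains) {
    ids <- c(ids, roots[[d]]); nm <- c(nm, paste0(d, " root"))
    dom <- c(dom, d); parents[[roots[[d]]]] <- character(0)
    depth <- c(depth, 0L)
  }
  names(depth) <- ids
  perDomain <- rep(nTerms %/% length(domains), length(domains))
  perDomain[seq_len(nTerms %% length(domains))] <-
    perDomain[seq_len(nTerms %% length(domains))] + 1L
  k <- 0L
  for (di in seq_along(domains)) {
    d <- domains[di]
    local_ids <- roots[[d]]
    for (i in seq_len(perDomain[di])) {
      k <- k + 1L
      id <- sprintf("GO:81%05d", k)
      eligible <- local_ids[depth[local_ids] < dagDepth]
      npar <- min(length(eligible), sample(1:2, 1))
      par <- sample(eligible, npar)
      parents[[id]] <- par
      depth[id] <- max(depth[par]) + 1L
      ids <- c(ids, id); nm <- c(nm, sprintf("synthetic term %d", k))
      dom <- c(dom, d)
      local_ids <- c(local_ids, id)
    }
  }
  # planted terms not yet in the DAG get attached under the first domain root
  for (t in setdiff(names(plantedTermMap), ids)) {
    parents[[t]] <- unname(roots[[1]])
    ids <- c(ids, t); nm <- c(nm, "planted term"); dom <- c(dom, domains[1])
  }
  dag <- new("GODag",
             terms = data.frame(id = ids, name = nm, domain = dom,
                                stringsAsFactors = FALSE),
             parents = parents)

  nonRoot <- setdiff(ids, unname(roots))
  ann <- setNames(vector("list", length(genes)), genes)
  rate <- matrix(annotationRate, length(genes), length(nonRoot),
                 dimnames = list(genes, nonRoot))
  for (t in names(plantedTermMap)) {
    tg <- intersect(plantedTermMap[[t]], genes)
    rate[tg, t] <- plantedRate
  }
  hit <- matrix(stats::runif(length(rate)), nrow(rate)) < rate
  for (gi in seq_along(genes))
    ann[[gi]] <- nonRoot[hit[gi, ]]
  list(dag = dag, annotations = ann)
}
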