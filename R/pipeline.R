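#' Pipeline configuration
#'
#' All study thresholds are defaults here, never hard-coded in stage code.
#' With `countsPath = NULL` the pipeline simulates counts (and, when
#' enrichment is enabled and no annotation files are given, GO annotations)
#' under the packaged study design.
#'
#' @param outdir output directory.
#' @param countsPath optional gene x sample count TSV (see
#'   [writeMatrixTsv()]).
#' @param designDir optional directory with `samples.tsv`/`phenotypes.tsv`
#'   (see [writeStudyDesign()]); required with `countsPath`.
#' @param annotationsPath optional 2-column gene/GO TSV.
#' @param oboPath optional OBO 1.2 ontology file.
#' @param seed integer seed controlling simulation.
#' @param simParams simulation parameters ([simulationParams()]).
#' @param minTotalCount correlation-stage row-sum filter.
#' @param minCpm,minSamples expression filter per comparison.
#' @param priorDf,priorCount dispersion shrinkage / fold-change prior.
#' @param minAbsLog2fc,maxFdr DEG thresholds.
#' @param foldThreshold,pseudocount Set B thresholds.
#' @param nodeSize,elimAlpha,reportAlpha GO enrichment settings.
#' @param exclusions informative-comparison exclusions (list of OTU pairs).
#' @param distances OTU distance matrix; `NULL` = packaged default.
#' @param enrichment run the GO stage.
#' @return named list of validated settings.
#' @export
pipelineConfig <- function(outdir = tempfile("electroDGE"),
                           countsPath = NULL, designDir = NULL,
                           annotationsPath = NULL, oboPath = NULL,
                           seed = 1L, simParams = simulationParams(),
                           minTotalCount = 10, minCpm = 1, minSamples = 2,
                           priorDf = 10, priorCount = 0.125,
                           minAbsLog2fc = 2, maxFdr = 0.001,
                           foldThreshold = 4, pseudocount = 1,
                           nodeSize = 10, elimAlpha = 0.01,
                           reportAlpha = 0.02,
                           exclusions = list(c("PMAG1", "PMAG2")),
                           distances = NULL, enrichment = TRUE) {
  stopifnot(minCpm > 0, minSamples > 0, minAbsLog2fc > 0, maxFdr > 0,
            foldThreshold > 0, nodeSize >= 1, elimAlpha > 0,
            reportAlpha > 0)
  if (!is.null(countsPath) && is.null(designDir))
    stop("countsPath requires designDir")
  for (p in c(countsPath, designDir, annotationsPath, oboPath))
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
  as.list(environment())
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys match the arguments of [pipelineConfig()]; `exclusions`
#' is a list of two-element OTU lists.  Unknown keys are an error.
#'
#' @param path YAML file.
#' @return configuration list (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), c(known, "simParams"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$exclusions))
    raw$exclusions <- lapply(raw$exclusions, unlist)
  if (!is.null(raw$simParams))
    raw$simParams <- do.call(simulationParams, raw$simParams)
  do.call(pipelineConfig, raw)
}

# Default planted GO term map for simulated data: one term per
# (feature, phenotype) class covering its planted genes.
.plantedTermMap <- function(truth, design) {
  keys <- .allSetKeys(design)
  m <- list()
  for (i in seq_along(keys)) {
    fp <- strsplit(keys[i], "|", fixed = TRUE)[[1]]
    g <- truth$gene[truth$class == "feature" & truth$feature == fp[1] &
                      truth$phenotype == fp[2]]
    if (length(g)) m[[sprintf("GO:82%05d", i)]] <- g
  }
  m
}

.loadInputs <- function(config) {
  if (is.null(config$countsPath)) {
    design <- makePaperDesign()
    x <- simulateCounts(design, config$simParams, seed = config$seed)
  } else {
    design <- readStudyDesign(config$designDir)
    counts <- readMatrixTsv(config$countsPath)
    storage.mode(counts) <- "integer"
    x <- EodExperiment(counts[, sampleIds(design), drop = FALSE], design)
  }
  ann <- dag <- NULL
  if (config$enrichment) {
    if (!is.null(config$annotationsPath) && !is.null(config$oboPath)) {
      ann <- readAnnotations(config$annotationsPath)
      dag <- readOBO(config$oboPath)
    } else if (is.null(config$countsPath)) {
      go <- simulateGO(rownames(x), nTerms = 90,
                       plantedTermMap = .plantedTermMap(truthTable(x),
                                                        studyDesign(x)),
                       domains = c("BP", "CC", "MF"),
                       seed = config$seed + 1000L)
      ann <- go$annotations
      dag <- go$dag
    }
  }
  list(x = x, annotations = ann, dag = dag)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Set B / Set C gene tables in the published per-gene layout: gene,
# centred log2(TMM-CPM + 1) per sample, feature, phenotype.
.setTable <- function(sets, exprCentered, design) {
  rows <- list()
  for (k in names(sets)) {
    if (!length(sets[[k]])) next
    fp <- strsplit(k, "|", fixed = TRUE)[[1]]
    sub <- exprCentered[sets[[k]], , drop = FALSE]
    df <- data.frame(gene = rownames(sub), as.data.frame(sub),
                     feature = fp[1], phenotype = fp[2],
                     stringsAsFactors = FALSE, check.names = FALSE)
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows))
    return(data.frame(gene = character(), feature = character(),
                      phenotype = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Stages: data loading or simulation; sample-correlation matrix; all
#' pairwise OTU comparisons (DEG and MA tables); Set A / A' / B / C
#' construction; GO enrichment for every up-regulated gene list (per
#' comparison with its own expressed-gene universe, Sets B and C with the
#' union universe); and a JSON run manifest.  Rerunning with an identical
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a list with the [EodExperiment-class], the
#'   correlation result, the gene-set bundle from [buildGeneSetFamily()],
#'   the enrichment tables and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- .loadInputs(config)
  x <- inputs$x
  design <- studyDesign(x)
  counts <- countMatrix(x)
  writeMatrixTsv(counts, file.path(config$outdir, "counts.tsv"))
  writeStudyDesign(design, file.path(config$outdir, "design"))
  if (!is.null(truthTable(x)))
    .writeTsv(truthTable(x), file.path(config$outdir, "truth.tsv"))

  corr <- sampleCorrelation(counts, config$minTotalCount)
  writeMatrixTsv(round(corr$r, 10),
                 file.path(config$outdir, "correlation.tsv"))
  .writeTsv(data.frame(position = seq_along(corr$ordering),
                       sample = colnames(counts)[corr$ordering]),
            file.path(config$outdir, "correlation_ordering.tsv"))

  distances <- if (is.null(config$distances)) defaultOtuDistances()
               else config$distances
  bundle <- buildGeneSetFamily(
    x, distance = distances, exclusions = config$exclusions,
    minCpm = config$minCpm, minSamples = config$minSamples,
    priorDf = config$priorDf, priorCount = config$priorCount,
    minAbsLog2fc = config$minAbsLog2fc, maxFdr = config$maxFdr,
    foldThreshold = config$foldThreshold, pseudocount = config$pseudocount)

  for (k in names(bundle$comparisons)) {
    res <- bundle$comparisons[[k]]
    slug <- gsub("|", "_vs_", k, fixed = TRUE)
    tab <- resultTable(res)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) signif(v, 10))
    .writeTsv(tab, file.path(config$outdir, paste0("deg_", slug, ".tsv")))
    ma <- maTable(res)
    ma[c("A", "logFC")] <- lapply(ma[c("A", "logFC")], signif, 10)
    .writeTsv(ma, file.path(config$outdir, paste0("ma_", slug, ".tsv")))
  }

  fam <- bundle$family
  .writeTsv(data.frame(gene = setA(fam)),
            file.path(config$outdir, "set_a.tsv"))
  .writeTsv(fam@informativeMap,
            file.path(config$outdir, "informative_comparisons.tsv"))
  exprC <- transformExpression(cpmValues(counts, tmmFactors(counts)))
  exprC <- signif(exprC, 10)
  attr(exprC, "scale") <- "log2p1-centered"
  for (nm in c("set_a_prime", "set_b", "set_c")) {
    sets <- switch(nm, set_a_prime = fam@setAPrime, set_b = fam@setB,
                   set_c = fam@setC)
    .writeTsv(.setTable(sets, exprC, design),
              file.path(config$outdir, paste0(nm, ".tsv")))
  }

  enrich <- list()
  if (config$enrichment && !is.null(inputs$dag)) {
    uni <- buildUniverses(bundle$universes)
    runGo <- function(sig, universe) {
      elimEnrichment(inputs$dag, inputs$annotations, sig, universe,
                     nodeSize = config$nodeSize,
                     elimAlpha = config$elimAlpha,
                     reportAlpha = config$reportAlpha)
    }
    for (k in names(bundle$comparisons)) {
      calls <- bundle$degCalls[[k]]
      res <- bundle$comparisons[[k]]
      for (o in comparedOtus(res)) {
        sig <- calls$gene[calls$upOtu == o]
        enrich[[paste0("comparison|", k, "|up_", o)]] <-
          runGo(sig, uni$perComparison[[k]])
      }
    }
    for (k in names(fam@setB))
      enrich[[paste0("set_b|", k)]] <- runGo(fam@setB[[k]], uni$union)
    for (k in names(fam@setC))
      enrich[[paste0("set_c|", k)]] <- runGo(fam@setC[[k]], uni$union)
    go <- do.call(rbind, lapply(names(enrich), function(n) {
      if (!nrow(enrich[[n]])) return(NULL)
      cbind(list_id = n, enrich[[n]])
    }))
    if (is.null(go))
      go <- data.frame(list_id = character(), term = character(),
                       name = character(), domain = character(),
                       annotated = integer(), significant = integer(),
                       expected = numeric(), p = numeric(),
                       genes = character(), stringsAsFactors = FALSE)
    go$expected <- signif(go$expected, 10)
    go$p <- signif(go$p, 10)
    .writeTsv(go, file.path(config$outdir, "go_enrichment.tsv"))
  }

  manifest <- list(
    package = "electroDGE",
    version = as.character(utils::packageVersion("electroDGE")),
    seed = config$seed,
    thresholds = config[c("minTotalCount", "minCpm", "minSamples",
                          "priorDf", "priorCount", "minAbsLog2fc", "maxFdr",
                          "foldThreshold", "pseudocount", "nodeSize",
                          "elimAlpha", "reportAlpha")],
    nGenes = nrow(counts),
    nSamples = ncol(counts),
    nComparisons = length(bundle$comparisons),
    genesPerComparison = lapply(bundle$universes, length),
    degsPerComparison = lapply(bundle$degCalls, nrow),
    setASize = length(setA(fam)),
    setCSizes = lapply(fam@setC, length),
    nSetCLists = length(fam@setC),
    nEnrichmentLists = length(enrich)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(experiment = x, correlation = corr, bundle = bundle,
                 enrichment = enrich, manifest = manifest))
}

#' Simulation-based recovery study
#'
#' Repeats simulate-then-analyse over `nSeeds` seeds and scores the
#' recovered gene sets against the simulation truth table: per-feature
#' Set C sensitivity (planted genes recovered under their own
#' feature/phenotype key), per-feature false-discovery proportion (`fdp`:
#' called genes that are not phenotype-linked at all; `strictKeyFdp`: any
#' call outside its exact planted key), and the depletion of OTU-specific
#' confounder genes in Set C relative to Set A (ratio of the confounder
#' proportions).  GO enrichment and file output are skipped.
#'
#' @param config a [pipelineConfig()] list (simulation settings are used;
#'   paths are ignored).
#' @param nSeeds number of seeds (`config$seed`, `config$seed + 1`, ...).
#' @return list with `perSeed` (data.frame: seed, feature, sensitivity,
#'   fdp, setCSize), `confounders` (data.frame: seed, ratio), and `summary`
#'   (per-feature medians plus `medianConfounderRatio`).
#' @export
runRecoveryStudy <- function(config = pipelineConfig(), nSeeds = 10) {
  design <- makePaperDesign()
  distances <- if (is.null(config$distances)) defaultOtuDistances()
               else config$distances
  perSeed <- list()
  confounders <- list()
  for (s in config$seed + seq_len(nSeeds) - 1L) {
    x <- simulateCounts(design, config$simParams, seed = s)
    truth <- truthTable(x)
    bundle <- buildGeneSetFamily(
      x, distance = distances, exclusions = config$exclusions,
      minCpm = config$minCpm, minSamples = config$minSamples,
      priorDf = config$priorDf, priorCount = config$priorCount,
      minAbsLog2fc = config$minAbsLog2fc, maxFdr = config$maxFdr,
      foldThreshold = config$foldThreshold,
      pseudocount = config$pseudocount)
    fam <- bundle$family
    featureGenes <- truth$gene[truth$class == "feature"]
    for (f in eodFeatures(design)) {
      keys <- names(fam@setC)[startsWith(names(fam@setC), paste0(f, "|"))]
      nPlanted <- 0L; nRecovered <- 0L; nCalled <- 0L
      nKeyFalse <- 0L; nNonFeature <- 0L
      for (k in keys) {
        p <- strsplit(k, "|", fixed = TRUE)[[1]][2]
        planted <- truth$gene[truth$class == "feature" &
                                truth$feature == f & truth$phenotype == p]
        called <- fam@setC[[k]]
        nPlanted <- nPlanted + length(planted)
        nRecovered <- nRecovered + length(intersect(called, planted))
        nCalled <- nCalled + length(called)
        nKeyFalse <- nKeyFalse + length(setdiff(called, planted))
        nNonFeature <- nNonFeature + length(setdiff(called, featureGenes))
      }
      perSeed[[length(perSeed) + 1L]] <- data.frame(
        seed = s, feature = f,
        sensitivity = if (nPlanted) nRecovered / nPlanted else NA_real_,
        # headline FDP: calls that are not phenotype-linked at all
        # (null or OTU-specific); strictKeyFdp additionally counts genes
        # planted for another feature or phenotype (cross-feature leakage
        # is expected where phenotype groups are nested, e.g. polarity
        # within triphasic complexity)
        fdp = if (nCalled) nNonFeature / nCalled else 0,
        strictKeyFdp = if (nCalled) nKeyFalse / nCalled else 0,
        setCSize = nCalled, stringsAsFactors = FALSE)
    }
    otuGenes <- truth$gene[truth$class == "otu"]
    allC <- unique(unlist(fam@setC, use.names = FALSE))
    propA <- if (length(setA(fam)))
      length(intersect(otuGenes, setA(fam))) / length(setA(fam)) else NA_real_
    propC <- if (length(allC))
      length(intersect(otuGenes, allC)) / length(allC) else 0
    ratio <- if (!is.na(propA) && propA > 0) propC / propA else NA_real_
    confounders[[length(confounders) + 1L]] <- data.frame(
      seed = s, propSetA = propA, propSetC = propC, ratio = ratio)
  }
  perSeed <- do.call(rbind, perSeed)
  confounders <- do.call(rbind, confounders)
  summary <- do.call(rbind, lapply(split(perSeed, perSeed$feature),
    function(d) data.frame(feature = d$feature[1],
                           medianSensitivity = stats::median(d$sensitivity),
                           medianFdp = stats::median(d$fdp),
                           medianStrictKeyFdp = stats::median(d$strictKeyFdp),
                           medianSetCSize = stats::median(d$setCSize))))
  rownames(summary) <- NULL
  list(perSeed = perSeed, confounders = confounders, summary = summary,
       medianConfounderRatio = stats::median(confounders$ratio,
                                             na.rm = TRUE))
}
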