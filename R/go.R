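#' @name GODag-accessors
#' @title Accessors for GODag
#' @param x a [GODag-class].
#' @param term a term identifier.
NULL

#' @rdname GODag-accessors
#' @export
setMethod("goTerms", "GODag", function(x) x@terms)

#' @rdname GODag-accessors
#' @export
setMethod("goParents", "GODag", function(x) x@parents)

#' All ancestors of a term (excluding the term itself)
#' @rdname GODag-accessors
#' @export
setMethod("goAncestors", "GODag", function(x, term) {
  seen <- character(0)
  frontier <- x@parents[[term]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(x@parents[frontier],
                                      use.names = FALSE)), seen)
  }
  sort(seen)
})

setMethod("show", "GODag", function(object) {
  cat("GODag:", nrow(object@terms), "terms;",
      sum(lengths(object@parents)), "edges\n")
  print(table(object@terms$domain))
})

.oboNamespace <- c(BP = "biological_process", CC = "cellular_component",
                   MF = "molecular_function")

#' Read a GO DAG from an OBO 1.2 file
#'
#' Minimal parser for `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`
#' and (optionally) `relationship: part_of` lines.  `part_of` edges are
#' treated as `is_a` for propagation when `partOfAsIsA = TRUE` (the
#' default).  Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @param partOfAsIsA treat part_of edges like is_a edges.
#' @return A [GODag-class].
#' @export
readOBO <- function(path, partOfAsIsA = TRUE) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  termStart <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1] - 1L, length(lines))
  names(ends) <- starts
  ids <- character(0); nms <- character(0); dom <- character(0)
  parents <- list()
  for (s in termStart) {
    blk <- lines[(s + 1):ends[as.character(s)]]
    grab <- function(tag) sub(paste0("^", tag, ": *"), "",
                              grep(paste0("^", tag, ": "), blk, value = TRUE))
    if (length(grab("is_obsolete")) && grab("is_obsolete")[1] == "true") next
    id <- grab("id")[1]
    isa <- sub(" *!.*$", "", grab("is_a"))
    if (partOfAsIsA) {
      rel <- grab("relationship")
      po <- sub(" *!.*$", "", sub("^part_of *", "",
                                  rel[startsWith(rel, "part_of")]))
      isa <- c(isa, po)
    }
    ns <- grab("namespace")
    ids <- c(ids, id)
    nms <- c(nms, if (length(grab("name"))) grab("name")[1] else id)
    dom <- c(dom, if (length(ns)) names(.oboNamespace)[.oboNamespace == ns[1]]
             else "BP")
    parents[[id]] <- unique(isa)
  }
  # drop edges to terms absent from the file
  parents <- lapply(parents, function(p) intersect(p, ids))
  new("GODag", terms = data.frame(id = ids, name = nms, domain = dom,
                                  stringsAsFactors = FALSE),
      parents = parents)
}

#' Write a GO DAG as an OBO 1.2 file
#'
#' @param dag a [GODag-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag@terms))) {
    id <- dag@terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag@terms$name[i]),
                 paste0("namespace: ", .oboNamespace[[dag@terms$domain[i]]]),
                 paste0("is_a: ", dag@parents[[id]]),
                 ""), con)
  }
  invisible(path)
}

#' Propagate direct annotations to ancestors (true-path rule)
#'
#' @param dag a [GODag-class].
#' @param direct named list, gene -> direct term ids.
#' @return named list, gene -> sorted closure (direct terms plus all their
#'   ancestors).  Unknown term ids are skipped with a warning.
#' @export
propagateAnnotations <- function(dag, direct) {
  known <- dag@terms$id
  bad <- setdiff(unique(unlist(direct, use.names = FALSE)), known)
  if (length(bad))
    warning("skipping unknown term ids: ", paste(bad, collapse = ", "))
  anc <- .ancestorClosure(dag)
  lapply(direct, function(ts) {
    ts <- intersect(ts, known)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
}

# term -> all ancestors, computed bottom-up in topological order.
.ancestorClosure <- function(dag) {
  ord <- .topoOrder(dag@parents)  # children before parents
  anc <- setNames(vector("list", length(ord)), ord)
  for (t in rev(ord)) {          # parents first
    ps <- dag@parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' One-sided Fisher over-representation p-value for a term
#'
#' Hypergeometric upper tail of the 2x2 table (significant/not x
#' annotated/not): the probability of at least the observed number of
#' annotated genes in the significant list.
#'
#' @param termGenes genes annotated to the term (within the universe).
#' @param sigGenes significant genes (subset of `universe`).
#' @param universe background gene list.
#' @return p-value.
#' @export
fisherEnrichment <- function(termGenes, sigGenes, universe) {
  stopifnot(all(sigGenes %in% universe))
  termGenes <- intersect(termGenes, universe)
  if (!length(termGenes)) stop("term has no annotations in the universe")
  k <- length(intersect(termGenes, sigGenes))
  stats::phyper(k - 1, length(termGenes),
                length(universe) - length(termGenes),
                length(sigGenes), lower.tail = FALSE)
}

#' DAG-aware enrichment with the elim algorithm
#'
#' Per ontology domain: terms with fewer than `nodeSize` universe
#' annotations are pruned; remaining terms are processed leaves-first
#' (reverse topological order); each term's Fisher test is computed after
#' removing the genes eliminated by its significant descendants (descendant
#' p < `elimAlpha` marks its annotated genes for elimination in all
#' ancestors).  Terms with p <= `reportAlpha` are reported, sorted by p
#' then term id.  Following common practice, the universe for a domain is
#' restricted to genes with at least one propagated annotation in that
#' domain.
#'
#' @param dag a [GODag-class].
#' @param annotations named list gene -> direct term ids (propagated
#'   internally).
#' @param sigGenes significant gene list.
#' @param universe background gene list.
#' @param nodeSize minimum universe annotations per tested term
#'   (default 10).
#' @param elimAlpha elimination threshold (default 0.01).
#' @param reportAlpha reporting threshold (default 0.02).
#' @return data.frame with `term`, `name`, `domain`, `annotated`,
#'   `significant`, `expected`, `p`, `genes` (comma-separated significant
#'   annotated genes); zero rows if nothing passes.
#' @export
elimEnrichment <- function(dag, annotations, sigGenes, universe,
                           nodeSize = 10, elimAlpha = 0.01,
                           reportAlpha = 0.02) {
  closure <- propagateAnnotations(dag, annotations)
  sigGenes <- intersect(sigGenes, universe)
  res <- list()
  for (d in sort(unique(dag@terms$domain))) {
    domTerms <- dag@terms$id[dag@terms$domain == d]
    # gene -> domain terms, restricted to the universe
    geneTerms <- lapply(closure[intersect(universe, names(closure))],
                        function(ts) intersect(ts, domTerms))
    geneTerms <- geneTerms[lengths(geneTerms) > 0]
    uniD <- names(geneTerms)
    sigD <- intersect(sigGenes, uniD)
    if (length(uniD) < 2) next
    term2gene <- .invertAnnotations(geneTerms)
    nAnn <- lengths(term2gene)
    keepTerms <- names(term2gene)[nAnn >= nodeSize]
    if (!length(keepTerms)) next
    ord <- .topoOrder(dag@parents)           # leaves first
    ord <- ord[ord %in% keepTerms]
    eliminated <- setNames(vector("list", length(keepTerms)), keepTerms)
    for (t in ord) {
      genes <- setdiff(term2gene[[t]], eliminated[[t]])
      k <- length(intersect(genes, sigD))
      K <- length(genes)
      p <- if (K == 0) 1 else
        stats::phyper(k - 1, K, length(uniD) - K, length(sigD),
                      lower.tail = FALSE)
      if (p < elimAlpha) {
        for (a in intersect(goAncestors(dag, t), keepTerms))
          eliminated[[a]] <- union(eliminated[[a]], term2gene[[t]])
      }
      if (p <= reportAlpha) {
        sigAnn <- sort(intersect(genes, sigD))
        res[[length(res) + 1L]] <- data.frame(
          term = t,
          name = dag@terms$name[dag@terms$id == t],
          domain = d,
          annotated = K,
          significant = k,
          expected = K * length(sigD) / length(uniD),
          p = p,
          genes = paste(sigAnn, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(term = character(), name = character(),
                      domain = character(), annotated = integer(),
                      significant = integer(), expected = numeric(),
                      p = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$domain, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.invertAnnotations <- function(geneTerms) {
  pairs <- data.frame(
    gene = rep(names(geneTerms), lengths(geneTerms)),
    term = unlist(geneTerms, use.names = FALSE),
    stringsAsFactors = FALSE)
  split(pairs$gene, pairs$term)
}

#' Enrichment universes for the pairwise comparisons and the set analyses
#'
#' The universe for each pairwise comparison is its own expressed-gene
#' list; the deduplicated union of those lists is the universe for all
#' Set B and Set C enrichment tests.
#'
#' @param perComparisonExpressed list of expressed-gene vectors.
#' @return list with `perComparison` (the input, genes sorted) and `union`
#'   (sorted deduplicated union).
#' @export
buildUniverses <- function(perComparisonExpressed) {
  stopifnot(length(perComparisonExpressed) > 0,
            all(lengths(perComparisonExpressed) > 0))
  per <- lapply(perComparisonExpressed, sort)
  list(perComparison = per,
       union = sort(unique(unlist(per, use.names = FALSE))))
}

#' Write / read a two-column gene -> GO annotation TSV
#'
#' @param annotations named list, gene -> term ids.
#' @param path file path.
#' @return `writeAnnotations` the path invisibly; `readAnnotations` a named
#'   list.
#' @export
writeAnnotations <- function(annotations, path) {
  df <- data.frame(
    gene = rep(names(annotations), lengths(annotations)),
    go = unlist(annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  split(df$go, df$gene)
}
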