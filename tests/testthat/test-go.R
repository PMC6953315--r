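test_that("OBO files round-trip through writer and parser", {
  dag <- makeTinyDag()
  path <- withr::local_tempfile(fileext = ".obo")
  writeOBO(dag, path)
  back <- readOBO(path)
  expect_equal(goTerms(back), goTerms(dag))
  expect_equal(goParents(back)[goTerms(dag)$id], goParents(dag))
})

test_that("part_of relationships can be treated as is_a edges", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: part",
               "namespace: biological_process",
               "relationship: part_of GO:0000001 ! root", ""), path)
  dag <- readOBO(path)
  expect_equal(goParents(dag)[["GO:0000002"]], "GO:0000001")
  dag2 <- readOBO(path, partOfAsIsA = FALSE)
  expect_length(goParents(dag2)[["GO:0000002"]], 0)
})

test_that("annotation propagation follows the true-path rule", {
  dag <- makeTinyDag()
  # leafB sits under a diamond: both parents share the root
  cl <- propagateAnnotations(dag, list(gA = "GO:0000005"))
  expect_equal(cl$gA, c("GO:0000001", "GO:0000002", "GO:0000003",
                        "GO:0000005"))
  # a root child closure is {term, root}
  cl2 <- propagateAnnotations(dag, list(gB = "GO:0000002"))
  expect_equal(cl2$gB, c("GO:0000001", "GO:0000002"))
  expect_equal(propagateAnnotations(dag, list()), list())
  expect_warning(propagateAnnotations(dag, list(g = "GO:9999999")),
                 "unknown")
})

test_that("Fisher enrichment equals the hypergeometric closed form", {
  universe <- paste0("g", 1:100)
  sig <- universe[1:10]
  termGenes <- universe[c(1:5, 11:15)]
  p <- fisherEnrichment(termGenes, sig, universe)
  expect_equal(p, oracleHyperTail(5, 10, 100, 10), tolerance = 1e-12)

  expect_equal(fisherEnrichment(universe, sig, universe), 1)
  expect_equal(fisherEnrichment(termGenes, character(0), universe), 1)
  expect_error(fisherEnrichment("absent", sig, universe), "no annotations")

  set.seed(70)
  for (i in 1:30) {
    N <- sample(10:60, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    tg <- sample(uni, K); sg <- sample(uni, n)
    k <- length(intersect(tg, sg))
    expect_equal(fisherEnrichment(tg, sg, uni),
                 oracleHyperTail(k, K, N, n), tolerance = 1e-11)
  }
})

test_that("elim on a flat DAG reduces to plain Fisher", {
  ids <- c("GO:0000001", paste0("GO:00000", 11:14))
  dag <- new("GODag",
             terms = data.frame(id = ids, name = ids, domain = "BP",
                                stringsAsFactors = FALSE),
             parents = c(list("GO:0000001" = character(0)),
                         setNames(replicate(4, "GO:0000001"), ids[-1])))
  set.seed(71)
  genes <- paste0("g", 1:80)
  ann <- lapply(setNames(genes, genes), function(g)
    sample(ids[-1], sample(1:3, 1)))
  sig <- genes[1:15]
  res <- elimEnrichment(dag, ann, sig, genes, nodeSize = 1,
                        elimAlpha = 0.01, reportAlpha = 1)
  cl <- propagateAnnotations(dag, ann)
  for (i in seq_len(nrow(res))) {
    t <- res$term[i]
    tg <- names(cl)[vapply(cl, function(ts) t %in% ts, logical(1))]
    expect_equal(res$p[i], fisherEnrichment(tg, sig, genes),
                 tolerance = 1e-12)
  }
})

test_that("elim suppresses a generic parent driven by its child", {
  # chain root -> parent -> child; the child concentrates the signal
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003")
  dag <- new("GODag",
             terms = data.frame(id = ids, name = ids, domain = "BP",
                                stringsAsFactors = FALSE),
             parents = list("GO:0000001" = character(0),
                            "GO:0000002" = "GO:0000001",
                            "GO:0000003" = "GO:0000002"))
  genes <- paste0("g", 1:200)
  ann <- c(lapply(setNames(genes[1:30], genes[1:30]),
                  function(g) "GO:0000003"),
           lapply(setNames(genes[31:70], genes[31:70]),
                  function(g) "GO:0000002"),
           lapply(setNames(genes[71:200], genes[71:200]),
                  function(g) "GO:0000001"))
  sig <- genes[1:25]
  res <- elimEnrichment(dag, ann, sig, genes, nodeSize = 5,
                        elimAlpha = 0.01, reportAlpha = 1)
  pChild <- res$p[res$term == "GO:0000003"]
  pParentElim <- res$p[res$term == "GO:0000002"]
  # plain Fisher for the parent (child genes included)
  pParentPlain <- fisherEnrichment(genes[1:70], sig, genes)
  expect_lt(pChild, 0.01)
  expect_gte(pParentElim, pParentPlain)
  expect_gt(pParentElim, 0.5)
})

test_that("reported terms respect nodeSize and the reporting threshold", {
  genes <- paste0("g", 1:300)
  planted <- genes[1:30]
  go <- simulateGO(genes, nTerms = 40, annotationRate = 0.05,
                   plantedTermMap = setNames(list(planted), "GO:8290000"),
                   plantedRate = 0.6, seed = 12)
  res <- elimEnrichment(go$dag, go$annotations, planted, genes,
                        nodeSize = 10, reportAlpha = 0.02)
  expect_true(all(res$annotated >= 10))
  expect_true(all(res$p <= 0.02))
  expect_true("GO:8290000" %in% res$term)
  # counts are mutually consistent as a 2x2 table
  expect_true(all(res$significant <= res$annotated))
  expect_true(all(res$significant <= length(planted)))
})

test_that("elim keeps the planted term and drops its generic ancestors", {
  wins <- 0
  for (s in 1:10) {
    genes <- paste0("g", 1:300)
    planted <- genes[1:30]
    go <- simulateGO(genes, nTerms = 30, annotationRate = 0.08,
                     plantedTermMap = setNames(list(planted), "GO:8290000"),
                     plantedRate = 0.7, seed = 300 + s)
    res <- elimEnrichment(go$dag, go$annotations, planted, genes,
                          nodeSize = 5, reportAlpha = 0.02)
    anc <- goAncestors(go$dag, "GO:8290000")
    ok <- "GO:8290000" %in% res$term && !any(anc %in% res$term)
    if (ok) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("universes combine per-comparison lists into a union", {
  u <- buildUniverses(list(a = c("b", "a"), b = c("c", "b")))
  expect_equal(u$perComparison$a, c("a", "b"))
  expect_equal(u$union, c("a", "b", "c"))
  u1 <- buildUniverses(list(x = c("q", "p")))
  expect_equal(u1$union, c("p", "q"))
  expect_gte(length(u$union), max(lengths(u$perComparison)))
  expect_error(buildUniverses(list(character(0))))
})

test_that("annotation TSV round-trips", {
  ann <- list(g1 = c("GO:0000002", "GO:0000004"), g2 = "GO:0000003")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(ann, path)
  expect_equal(readAnnotations(path), ann)
})
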