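toySpec <- function(nA = 2, nB = 2) {
  d <- makeToyDesign(nA, nB)
  comparisonSpec(d, "OTUA", "OTUB")
}

test_that("comparison specs flag contrasted features correctly", {
  d <- makePaperDesign()
  s <- comparisonSpec(d, "PKINGN", "PKINGP")
  expect_equal(unname(s$contrasts),
               c(FALSE, TRUE, FALSE))  # complexity only; polarity N/A
  s2 <- comparisonSpec(d, "PKINGP", "PMAG1")
  expect_equal(unname(s2$contrasts), c(FALSE, FALSE, TRUE))
  s3 <- comparisonSpec(d, "PKINGP", "PMAG2")
  expect_false(any(s3$contrasts))
  s4 <- comparisonSpec(d, "PMAG2", "PSN3")
  expect_equal(unname(s4$contrasts), c(TRUE, TRUE, FALSE))
  expect_error(comparisonSpec(d, "PKINGN", "PKINGN"))
})

test_that("expression filter keeps genes with CPM above threshold in
          enough samples", {
  spec <- toySpec(2, 2)
  libs <- 1e6
  # per-sample libraries equal 1e6 via a dominant filler gene
  m <- cm(15, 9, 0, 0,
          15, 9, 0, 0,
          0, 9, 0, 0,
          0, 9, 0, 0, nrow = 4,
          samples = c("A1", "A2", "B1", "B2"))
  filler <- libs - colSums(m)
  m <- rbind(m, filler = filler)
  # g1: CPM (15,15,0,0) -> kept (2 samples > 1)
  # g2: CPM (9,9,9,9)   -> kept
  # g3: CPM (0,...)     -> dropped; g4 idem
  kept <- filterExpressed(m, spec, minCpm = 10, minSamples = 2)
  expect_true("g1" %in% kept)
  expect_false("g2" %in% kept)
  kept2 <- filterExpressed(m, spec, minCpm = 1, minSamples = 2)
  expect_setequal(setdiff(kept2, "filler"), c("g1", "g2"))
  kept3 <- filterExpressed(m, spec, minCpm = 1, minSamples = 3)
  expect_false("g1" %in% kept3)
  expect_true("g2" %in% kept3)
})

test_that("common dispersion hits the lower bound on replicated columns", {
  spec <- toySpec(2, 2)
  m <- rbind(g1 = c(50, 50, 80, 80),
             g2 = c(10, 10, 30, 30),
             g3 = c(200, 200, 100, 100))
  colnames(m) <- c("A1", "A2", "B1", "B2")
  est <- estimateCommonDispersion(m, spec, effLibs = setNames(
    rep(1000, 4), colnames(m)))
  expect_equal(est, 1e-6)
})

test_that("common dispersion is consistent on simulated data", {
  spec <- toySpec(2, 2)
  eq <- setNames(rep(1e5, 4), c("A1", "A2", "B1", "B2"))
  set.seed(31)
  mPois <- matrix(rpois(2000 * 4, 100), 2000,
                  dimnames = list(paste0("g", 1:2000), names(eq)))
  expect_lte(estimateCommonDispersion(mPois, spec, eq), 0.01)

  set.seed(32)
  mNb <- matrix(rnbinom(2000 * 4, mu = 100, size = 5), 2000,
                dimnames = list(paste0("g", 1:2000), names(eq)))
  est <- estimateCommonDispersion(mNb, spec, eq)
  expect_gte(est, 0.15)
  expect_lte(est, 0.25)
})

test_that("tagwise dispersion shrinks toward the common value", {
  spec <- toySpec(3, 3)
  eq <- setNames(rep(1e5, 6), c("A1", "A2", "A3", "B1", "B2", "B3"))
  set.seed(33)
  m <- matrix(rnbinom(300 * 6, mu = 80, size = 10), 300,
              dimnames = list(paste0("g", 1:300), names(eq)))
  common <- estimateCommonDispersion(m, spec, eq)

  tw0 <- estimateTagwiseDispersion(m, spec, common, priorDf = 0,
                                   effLibs = eq)
  tw10 <- estimateTagwiseDispersion(m, spec, common, priorDf = 10,
                                    effLibs = eq)
  tw40 <- estimateTagwiseDispersion(m, spec, common, priorDf = 40,
                                    effLibs = eq)
  twInf <- estimateTagwiseDispersion(m, spec, common, priorDf = Inf,
                                     effLibs = eq)
  expect_equal(unname(twInf), rep(common, 300), tolerance = 1e-6)
  # increasing priorDf moves estimates weakly toward common
  d0 <- abs(log(pmax(tw0, 1e-6)) - log(common))
  d10 <- abs(log(pmax(tw10, 1e-6)) - log(common))
  d40 <- abs(log(pmax(tw40, 1e-6)) - log(common))
  expect_true(mean(d10 <= d0 + 1e-6) > 0.95)
  expect_true(mean(d40 <= d10 + 1e-6) > 0.95)
})

test_that("unshrunk tagwise dispersion matches the likelihood oracle", {
  spec <- toySpec(3, 3)
  eq <- setNames(rep(1e5, 6), c("A1", "A2", "A3", "B1", "B2", "B3"))
  cases <- list(c(5, 50, 20, 10, 60, 25),
                c(100, 140, 120, 80, 90, 100),
                c(3, 4, 5, 40, 45, 50))
  for (y in cases) {
    m <- matrix(y, 1, dimnames = list("g1", names(eq)))
    est <- estimateTagwiseDispersion(m, spec, common = 0.1, priorDf = 0,
                                     effLibs = eq)
    opt <- optimize(function(phi)
      oracleCondLogLik(y[1:3], y[4:6], phi),
      interval = c(1e-6, 10), maximum = TRUE, tol = 1e-9)
    want <- if (oracleCondLogLik(y[1:3], y[4:6], 1e-6) >= opt$objective)
      1e-6 else opt$maximum
    expect_equal(unname(est), want, tolerance = 1e-4)
  }
})

test_that("exact test is 1 for balanced genes and matches enumeration", {
  spec <- toySpec(2, 2)
  eq <- setNames(rep(1e4, 4), c("A1", "A2", "B1", "B2"))
  m <- cm(30, 30, 30, 30, nrow = 1, samples = names(eq))
  res <- exactTest(m, spec, dispersions = 0.1, effLibs = eq)
  expect_equal(resultTable(res)$PValue, 1)

  # random splits vs the dnbinom-enumeration oracle
  set.seed(40)
  for (i in 1:20) {
    z <- sample(5:60, 1)
    zA <- sample(0:z, 1)
    for (phi in c(0, 0.1, 0.5)) {
      mine <- electroDGE:::.exactNbPval(zA, z - zA, 2, 2, phi)
      expect_equal(mine, oracleExactP(zA, z - zA, 2, 2, phi),
                   tolerance = 1e-10)
    }
  }
})

test_that("Poisson-limit exact test equals the conditional binomial", {
  # total 6 split (6,0) with equal libraries and two single-sample groups
  p <- electroDGE:::.exactNbPval(6, 0, 1, 1, 0)
  # two-sided binomial by enumeration: all outcomes with prob <= P(6)
  pr <- dbinom(0:6, 6, 0.5)
  expect_equal(p, sum(pr[pr <= pr[7] * (1 + 1e-12)]))
  expect_equal(p, 2 * (0.5)^6)
})

test_that("exact test is symmetric under group swap with sign-flipped
          logFC", {
  d <- makeToyDesign(2, 2)
  specAB <- comparisonSpec(d, "OTUA", "OTUB")
  specBA <- comparisonSpec(d, "OTUB", "OTUA")
  eq <- setNames(rep(2e4, 4), c("A1", "A2", "B1", "B2"))
  m <- cm(10, 14, 60, 75,
          40, 42, 35, 30, nrow = 2, samples = names(eq))
  rAB <- resultTable(exactTest(m, specAB, 0.1, eq))
  rBA <- resultTable(exactTest(m, specBA, 0.1, eq))
  expect_equal(rAB$PValue, rBA$PValue, tolerance = 1e-12)
  expect_equal(rAB$logFC, -rBA$logFC, tolerance = 1e-12)
})

test_that("BH adjustment matches the closed form and the oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(50)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
  expect_error(bhAdjust(c(0.1, NaN)), "NaN")
})

test_that("DEG calling uses strict thresholds and the sign convention", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    logFC = c(2.0, -3, 2.5, 4),
                    logCPM = 5, PValue = c(1e-6, 1e-6, 1e-6, 1e-6),
                    FDR = c(1e-5, 1e-5, 0.001, 1e-5),
                    stringsAsFactors = FALSE)
  res <- new("DGEResult", table = tab, otuA = "X", otuB = "Y",
             samplesA = "a", samplesB = "b",
             commonDispersion = 0.1, dispersion = c(g1 = 0.1))
  calls <- callDegs(res)
  # g1: logFC exactly 2 -> excluded; g3: FDR exactly 0.001 -> excluded
  expect_setequal(calls$gene, c("g2", "g4"))
  expect_equal(calls$upOtu[calls$gene == "g2"], "Y")
  expect_equal(calls$direction[calls$gene == "g4"], "up_in_X")
})

test_that("MA table flags FDR < 0.05 independently of DEG thresholds", {
  tab <- data.frame(gene = c("g1", "g2"), logFC = c(1, 2), logCPM = c(3, 4),
                    PValue = c(0.001, 0.1), FDR = c(0.04, 0.2),
                    stringsAsFactors = FALSE)
  res <- new("DGEResult", table = tab, otuA = "X", otuB = "Y",
             samplesA = "a", samplesB = "b",
             commonDispersion = 0.1, dispersion = c(g1 = 0.1))
  ma <- maTable(res)
  expect_identical(ma$significant, c(TRUE, FALSE))
  emptyRes <- new("DGEResult", table = tab[0, ], otuA = "X", otuB = "Y",
                  samplesA = "a", samplesB = "b",
                  commonDispersion = 0.1, dispersion = numeric(0))
  expect_equal(nrow(maTable(emptyRes)), 0)
})

test_that("planted strong effects are detected with high power", {
  d <- makeToyDesign(2, 2)
  hits <- 0; n <- 0
  for (s in 1:3) {
    par <- simulationParams(nGenes = 400, nFeatureGenes = 40,
                            featureEffectFold = 8, nOtuGenes = 0,
                            baselineLog2CpmRange = c(6, 9))
    x <- simulateCounts(d, par, seed = 200 + s)
    res <- runComparison(x, "OTUA", "OTUB")
    calls <- callDegs(res)
    tr <- truthTable(x)
    planted <- tr$gene[tr$class == "feature"]
    hits <- hits + length(intersect(calls$gene, planted))
    n <- n + length(planted)
  }
  expect_gte(hits / n, 0.9)
})
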