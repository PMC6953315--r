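# Independent oracles and small fixtures used across the suite.
# Each oracle re-derives the quantity from its definition by a different
# route than the package implementation.

# --- TMM: literal step-by-step trimmed weighted mean -----------------------

# Stable rank: position in a stable ascending sort.
stableRank <- function(x) {
  r <- integer(length(x))
  r[order(x, seq_along(x))] <- seq_along(x)
  r
}

# Type-7 upper quartile computed from its definition.
upperQuartile <- function(x) {
  x <- sort(x)
  h <- (length(x) - 1) * 0.75 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

oracleTmm <- function(counts, logratioTrim = 0.30, sumTrim = 0.05) {
  libs <- colSums(counts)
  stopifnot(all(libs > 0))
  uq <- apply(t(t(counts) / libs) * 1e6, 2, upperQuartile)
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (i in seq_len(ncol(counts))) {
    o <- counts[, i]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    if (!any(keep)) { f[i] <- 1; next }
    po <- o[keep] / libs[i]
    pr <- r[keep] / libs[ref]
    M <- log2(po / pr)
    A <- 0.5 * log2(po * pr)
    # asymptotic (delta-method) variance of M
    v <- (libs[i] - o[keep]) / (libs[i] * o[keep]) +
      (libs[ref] - r[keep]) / (libs[ref] * r[keep])
    if (max(abs(M)) < 1e-6) { f[i] <- 1; next }
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1;      hiA <- n + 1 - loA
    rM <- stableRank(M); rA <- stableRank(A)
    sel <- which(rM >= loM & rM <= hiM & rA >= loA & rA <= hiA)
    if (!length(sel)) { f[i] <- 1; next }
    w <- 1 / v[sel]
    fi <- 2^(sum(w * M[sel]) / sum(w))
    f[i] <- if (is.finite(fi) && fi > 0) fi else 1
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# --- Exact NB test: enumeration of the conditional outcome space -----------

# Conditional distribution of the group-A total given the grand total, via
# R's dnbinom on the group sums (any common mean cancels).
oracleExactP <- function(zA, zB, nA, nB, phi) {
  z <- zA + zB
  if (z == 0) return(1)
  a <- 0:z
  if (phi < 1e-10) {
    pr <- dbinom(a, z, nA / (nA + nB))
  } else {
    pr <- dnbinom(a, size = nA / phi, mu = nA * 10) *
      dnbinom(z - a, size = nB / phi, mu = nB * 10)
    pr <- pr / sum(pr)
  }
  pObs <- pr[zA + 1]
  min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

# Per-gene conditional NB log-likelihood via dnbinom (sum distribution in
# the denominator); independent of the lgamma route in the package.
oracleCondLogLik <- function(yA, yB, phi) {
  ll <- 0
  for (y in list(yA, yB)) {
    n <- length(y)
    if (n < 2) next
    ll <- ll + sum(dnbinom(y, size = 1 / phi, mu = 10, log = TRUE)) -
      dnbinom(sum(y), size = n / phi, mu = n * 10, log = TRUE)
  }
  ll
}

# --- BH step-up from the definition ---------------------------------------

oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o[rank_i:m]] * m / (rank_i:m)))
  }
  q
}

# --- Hypergeometric upper tail by explicit summation -----------------------

oracleHyperTail <- function(k, K, N, n) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# --- Fixtures ---------------------------------------------------------------

# Minimal two-OTU design with a single feature.
makeToyDesign <- function(nA = 2, nB = 2) {
  samples <- c(paste0("A", seq_len(nA)), paste0("B", seq_len(nB)))
  otu <- setNames(rep(c("OTUA", "OTUB"), c(nA, nB)), samples)
  phen <- data.frame(duration = c("long", "short"),
                     row.names = c("OTUA", "OTUB"),
                     stringsAsFactors = FALSE)
  StudyDesign(samples, otu, phen)
}

# Named count matrix helper.
cm <- function(..., nrow, samples = NULL) {
  m <- matrix(c(...), nrow = nrow)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m)))
                 else samples
  m
}

# A tiny hand-built DAG:  root -> mid1, mid2; mid1 -> leafA; mid1,mid2 -> leafB
# (leafB is the diamond child with two parents sharing the root).
makeTinyDag <- function(domain = "BP") {
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004",
           "GO:0000005")
  new("GODag",
      terms = data.frame(id = ids,
                         name = c("root", "mid1", "mid2", "leafA", "leafB"),
                         domain = domain, stringsAsFactors = FALSE),
      parents = list("GO:0000001" = character(0),
                     "GO:0000002" = "GO:0000001",
                     "GO:0000003" = "GO:0000001",
                     "GO:0000004" = "GO:0000002",
                     "GO:0000005" = c("GO:0000002", "GO:0000003")))
}
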