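# Independent oracles: deliberately naive implementations kept separate
# from the package's code paths.

# Floyd-Warshall all-pairs shortest paths on edge lengths 1/weight,
# with strength / farness / nodal efficiency / global efficiency.
fwMetricsOracle <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  list(strength = rowSums(w),
       farness = rowSums(d) / (n - 1),
       nodalEfficiency = rowSums(inv) / (n - 1),
       globalEfficiency = sum(inv) / (n * (n - 1)))
}

# Prim's algorithm for the maximum-weight spanning tree; returns a
# logical adjacency matrix of tree edges.
primMaxTreeOracle <- function(w) {
  n <- nrow(w)
  inTree <- c(TRUE, rep(FALSE, n - 1))
  tree <- matrix(FALSE, n, n)
  while (!all(inTree)) {
    best <- -Inf
    bi <- bj <- NA
    for (i in which(inTree)) {
      for (j in which(!inTree)) {
        if (w[i, j] > best) {
          best <- w[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    tree[bi, bj] <- tree[bj, bi] <- TRUE
    inTree[bj] <- TRUE
  }
  tree
}

# Naive MODWT pyramid: explicit per-coefficient loops, reflection
# boundary, boundary coefficients dropped (same convention, independent
# code path).
naiveModwtOracle <- function(x, j) {
  s3 <- sqrt(3)
  g <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)) / sqrt(2)
  h <- c(g[4], -g[3], g[2], -g[1])
  v <- c(x, rev(x))
  n <- length(v)
  for (lev in seq_len(j)) {
    off <- 2^(lev - 1)
    wv <- numeric(n)
    vv <- numeric(n)
    for (t in seq_len(n)) {
      for (l in 0:3) {
        idx <- ((t - 1 - off * l) %% n) + 1
        wv[t] <- wv[t] + h[l + 1] * v[idx]
        vv[t] <- vv[t] + g[l + 1] * v[idx]
      }
    }
    v <- vv
  }
  nOrig <- length(x)
  nb <- (2^j - 1) * 3
  wv[(nb + 1):nOrig]
}

makeConn <- function(v, id = "t") {
  new("ConnectivityMatrix", subjectId = id, values = v)
}

# random all-positive symmetric "correlation-like" matrix (complete
# graph, hence connected under any positive threshold)
randPosMatrix <- function(n, seed) {
  set.seed(seed)
  v <- matrix(runif(n * n, 0.05, 1), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  v
}

# small carrier+FTD cohort config used by simulation-study tests
# (single site/gene variants fall back to the OLS path)
bpSimConfig <- function(seed, preSlope, postSlope, noiseSd = 0.012) {
  cohortConfig(nGeneNegative = 0L, nSites = 1L, geneLabels = "GRN",
               seed = seed, strengthOnsetSlope = 0,
               carrierEfficiencyOffset = 0,
               preOnsetEfficiencySlope = preSlope,
               postOnsetEfficiencySlope = postSlope,
               efficiencyNoiseSd = noiseSd,
               siteSdEfficiency = 0, geneSdEfficiency = 0)
}

bpSimOnce <- function(cfg, outcome = "true_efficiency_score") {
  ch <- generateCohort(cfg, detail = "metadata")
  tbl <- analysisTable(ch$subjects,
                       ch$groundTruth$perSubject[, c("subject_id", outcome)])
  fitBreakpointModel(tbl, outcome)
}

# regional analysis table from a covariance-level cohort
regionalTableFromCohort <- function(cohort) {
  gt <- cohort$groundTruth
  rs <- gt$regionalStrength
  reg <- data.frame(
    subject_id = rep(rownames(rs), each = ncol(rs)),
    node = rep(seq_len(ncol(rs)), times = nrow(rs)),
    strength = as.vector(t(rs)))
  reg <- merge(reg, cohort$subjects[, c("subject_id", "group", "age",
                                        "site", "gene")],
               by = "subject_id")
  reg$hub_flag <- reg$node %in% gt$hubSet
  reg
}

hubSimConfig <- function(seed, ftdHubScale) {
  cohortConfig(nGeneNegative = 0L, nCarrier = 68L, nFtd = 24L,
               nRegions = 30L, seed = seed, ftdHubScale = ftdHubScale,
               strengthOnsetSlope = 0, carrierEfficiencyOffset = 0,
               preOnsetEfficiencySlope = 0, postOnsetEfficiencySlope = 0,
               ftdStrengthSpread = 0)
}

hubSimOnce <- function(seed, ftdHubScale) {
  ch <- generateCohort(hubSimConfig(seed, ftdHubScale),
                       detail = "covariance")
  suppressWarnings(hubGapInteraction(regionalTableFromCohort(ch)))
}
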