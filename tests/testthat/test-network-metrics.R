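# Graph construction, strength / path-length metrics, nulls, hubs.

test_that("density-1 build keeps the complete graph with correlation weights", {
  v <- randPosMatrix(8, 1)
  g <- buildGraph(makeConn(v), "zero", 1.0)
  w <- graphWeights(g)
  expect_equal(w[upper.tri(w)], v[upper.tri(v)])
  expect_equal(edgeDensity(g), 1)
  expect_equal(diag(w), rep(0, 8))
})

test_that("thresholded build hits the target edge count and contains the MST", {
  v <- randPosMatrix(100, 2)
  g <- buildGraph(makeConn(v), "zero", 0.10)
  w <- graphWeights(g)
  m <- sum(w[upper.tri(w)] > 0)
  expect_equal(m, 495)
  tree <- primMaxTreeOracle(v)
  expect_equal(sum(tree[upper.tri(tree)]), 99)
  expect_true(all(w[tree] > 0))     # every backbone edge retained
})

test_that("an all-negative matrix cannot be connected under the zero policy", {
  v <- matrix(-0.5, 5, 5)
  diag(v) <- 1
  expect_error(buildGraph(makeConn(v), "zero", 0.5), "cannot connect")
  gAbs <- buildGraph(makeConn(v), "absolute", 1.0)
  expect_equal(max(graphWeights(gAbs)), 0.5)
})

test_that("nodal metrics match hand-computed values on tiny graphs", {
  # 3-node unit complete graph
  v1 <- matrix(1, 3, 3)
  g1 <- buildGraph(v1, "zero", 1.0, subjectId = "c3")
  m1 <- computeNodalMetrics(g1)
  expect_equal(m1$strength, rep(2, 3))
  expect_equal(m1$farness, rep(1, 3))
  expect_equal(m1$nodal_efficiency, rep(1, 3))
  gm1 <- computeGlobalMetrics(g1, normalize = FALSE)
  expect_equal(gm1@globalEfficiencyRaw, 1)

  # path A-B (w=1), B-C (w=0.5): d(AB)=1, d(BC)=2, d(AC)=3
  v2 <- diag(3)
  v2[1, 2] <- v2[2, 1] <- 1
  v2[2, 3] <- v2[3, 2] <- 0.5
  g2 <- buildGraph(v2, "zero", 1.0, subjectId = "p3")
  m2 <- computeNodalMetrics(g2)
  expect_equal(m2$strength, c(1, 1.5, 0.5))
  expect_equal(m2$farness, c(2, 1.5, 2.5))
  expect_equal(m2$nodal_efficiency,
               c((1 + 1 / 3) / 2, (1 + 1 / 2) / 2, (1 / 2 + 1 / 3) / 2))
  gm2 <- computeGlobalMetrics(g2, normalize = FALSE)
  expect_equal(gm2@globalEfficiencyRaw, (1 + 1 / 2 + 1 / 3) / 3)
  expect_equal(gm2@connectionStrengthTotal, 2 * (1 + 0.5))
})

test_that("metrics are invariant under node relabeling", {
  v <- randPosMatrix(12, 3)
  g <- buildGraph(makeConn(v), "zero", 0.4)
  m <- computeNodalMetrics(g)
  set.seed(4)
  p <- sample(12)
  gp <- buildGraph(makeConn(v[p, p]), "zero", 0.4)
  mp <- computeNodalMetrics(gp)
  expect_equal(mp$strength, m$strength[p])
  expect_equal(mp$farness, m$farness[p])
  expect_equal(mp$nodal_efficiency, m$nodal_efficiency[p])
})

test_that("the handshake identity holds on arbitrary graphs", {
  for (s in 1:3) {
    v <- randPosMatrix(15, 10 + s)
    g <- buildGraph(makeConn(v), "zero", 0.3)
    gm <- computeGlobalMetrics(g, normalize = FALSE)
    w <- graphWeights(g)
    expect_equal(gm@connectionStrengthTotal, 2 * sum(w[upper.tri(w)]))
  }
})

test_that("uniform weight scaling scales metrics and cancels in normalization", {
  v <- randPosMatrix(25, 5)
  g <- buildGraph(makeConn(v), "zero", 0.3)
  spec <- nullEnsembleSpec(nNulls = 20, seed = 6)
  gm <- computeGlobalMetrics(g, generateNullEnsemble(g, spec))
  g2 <- new("BrainGraph", subjectId = "s", weights = 3 * graphWeights(g),
            edgeDensity = g@edgeDensity, negativePolicy = "zero",
            targetDensity = g@targetDensity)
  gm2 <- computeGlobalMetrics(g2, generateNullEnsemble(g2, spec))
  expect_equal(gm2@connectionStrengthTotal, 3 * gm@connectionStrengthTotal)
  expect_equal(gm2@globalEfficiencyRaw, 3 * gm@globalEfficiencyRaw)
  expect_equal(gm2@globalEfficiencyNormalized,
               gm@globalEfficiencyNormalized, tolerance = 1e-10)
})

test_that("null graphs preserve degrees and the edge-weight multiset", {
  v <- randPosMatrix(30, 7)
  g <- buildGraph(makeConn(v), "zero", 0.2)
  w <- graphWeights(g)
  nulls <- generateNullEnsemble(g, nullEnsembleSpec(nNulls = 10, seed = 3))
  for (nb in nulls) {
    wn <- graphWeights(nb)
    expect_equal(colSums(wn > 0), colSums(w > 0))
    expect_equal(sort(wn[upper.tri(wn) & wn > 0]),
                 sort(w[upper.tri(w) & w > 0]))
    expect_true(resilnet:::adjacencyConnected(wn))
  }
  # seeded determinism
  n2 <- generateNullEnsemble(g, nullEnsembleSpec(nNulls = 10, seed = 3))
  expect_identical(lapply(nulls, graphWeights), lapply(n2, graphWeights))
})

test_that("a complete input graph only permutes weights in its nulls", {
  v <- randPosMatrix(7, 8)
  g <- buildGraph(makeConn(v), "zero", 1.0)
  nulls <- generateNullEnsemble(g, nullEnsembleSpec(nNulls = 5, seed = 2))
  w <- graphWeights(g)
  for (nb in nulls) {
    wn <- graphWeights(nb)
    expect_true(all((wn > 0) == (w > 0)))
    expect_equal(sort(wn[upper.tri(wn)]), sort(w[upper.tri(w)]))
  }
})

test_that("hub identification applies a strict 2-SD rule", {
  expect_equal(identifyHubs(rep(3, 50)), integer(0))
  set.seed(9)
  x <- pmin(pmax(rnorm(100), -2), 2)   # bounded noise floor
  x[37] <- 5
  expect_equal(identifyHubs(x), 37L)
  expect_error(identifyHubs(1), "at least 2")
  # threshold is strict: a value exactly at mean + 2 SD is not a hub
  y <- c(0, 0, 0, 0)
  y[4] <- mean(y[1:3])   # degenerate guard exercised above; strictness:
  z <- c(1, 2, 3)
  thr <- mean(z) + 2 * stats::sd(z)
  expect_false(3 %in% identifyHubs(c(z[1:2], thr)))
})

test_that("weakening hub-incident edges shrinks the hub strength gap", {
  v <- randPosMatrix(40, 11)
  hubs <- 1:5
  v[hubs, ] <- v[hubs, ] * 1.8
  v[, hubs] <- t(v[hubs, ])
  diag(v) <- 1
  gap <- function(w) {
    s <- rowSums(w) - diag(w)
    mean(s[hubs]) - mean(s[-hubs])
  }
  v2 <- v
  inc <- outer(seq_len(40) %in% hubs, seq_len(40) %in% hubs, "|")
  diag(inc) <- FALSE
  v2[inc] <- v2[inc] * 0.7
  expect_lt(gap(v2), gap(v))
})
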