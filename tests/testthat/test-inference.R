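# Mixed-effects contrasts, breakpoint regression, associations.

metaTable <- function(cfg, outcome = "true_strength") {
  ch <- generateCohort(cfg, detail = "metadata")
  analysisTable(ch$subjects,
                ch$groundTruth$perSubject[, c("subject_id", outcome)])
}

test_that("degenerate random factors reduce to the OLS ANCOVA estimate", {
  cfg <- cohortConfig(nSites = 1L, geneLabels = "GRN", seed = 12,
                      ftdStrengthScale = 0.85, strengthOnsetSlope = 0)
  tbl <- metaTable(cfg)
  cr <- fitGroupContrast(tbl, "true_strength", c("ftd", "carrier"))
  expect_equal(cr@method, "ols")
  expect_match(cr@note, "dropped")
  # closed-form OLS oracle
  fit <- stats::lm(true_strength ~ factor(group, levels = c(
    "gene_negative", "carrier", "ftd")) + age, data = tbl)
  cf <- stats::coef(fit)
  oracle <- unname(cf[3] - cf[2])
  expect_equal(cr@estimate, oracle, tolerance = 1e-6)
  expect_equal(cr@df, stats::df.residual(fit))
})

test_that("a constant outcome yields a zero, flagged contrast", {
  cfg <- cohortConfig(nGeneNegative = 6L, nCarrier = 6L, nFtd = 4L,
                      seed = 2)
  tbl <- metaTable(cfg)
  tbl$flat <- 7
  cr <- fitGroupContrast(tbl, "flat", c("ftd", "carrier"))
  expect_equal(cr@estimate, 0)
  expect_true(is.na(cr@p))
  expect_match(cr@note, "constant")
})

test_that("Satterthwaite df never exceed the OLS residual df", {
  cfg <- cohortConfig(seed = 5)
  tbl <- metaTable(cfg)
  cr <- suppressWarnings(
    fitGroupContrast(tbl, "true_strength", c("ftd", "carrier")))
  expect_equal(cr@method, "lmm")
  expect_lte(cr@df, nrow(tbl) - 4)    # intercept + 2 group terms + age
  expect_gt(cr@df, 0)
})

test_that("a missing contrast group raises", {
  cfg <- cohortConfig(nGeneNegative = 10L, nCarrier = 10L, nFtd = 0L,
                      seed = 3)
  tbl <- metaTable(cfg)
  expect_error(fitGroupContrast(tbl, "true_strength", c("ftd", "carrier")),
               "absent")
})

test_that("noiseless linear data show no breakpoint", {
  cfg <- bpSimConfig(4, preSlope = 0.003, postSlope = 0.003, noiseSd = 0)
  bp <- suppressWarnings(bpSimOnce(cfg))
  expect_equal(bp@slopeChange, 0, tolerance = 1e-8)
  expect_equal(bp@levelChange, 0, tolerance = 1e-8)
  expect_gt(bp@pBreakpoint, 0.05)
})

test_that("the breakpoint model requires data on both sides of the knot", {
  cfg <- cohortConfig(nGeneNegative = 0L, nCarrier = 20L, nFtd = 0L,
                      seed = 6)
  ch <- generateCohort(cfg, detail = "metadata")
  tbl <- analysisTable(ch$subjects,
                       ch$groundTruth$perSubject[, c("subject_id",
                                                     "true_strength")])
  expect_error(fitBreakpointModel(tbl, "true_strength"), "beyond")
})

test_that("breakpoint estimator is consistent as n grows and noise shrinks", {
  bias <- function(nMult, noise) {
    cfg <- cohortConfig(nGeneNegative = 0L, nCarrier = 68L * nMult,
                        nFtd = 24L * nMult, nSites = 1L,
                        geneLabels = "GRN", seed = 30 + nMult,
                        strengthOnsetSlope = 0, carrierEfficiencyOffset = 0,
                        preOnsetEfficiencySlope = 0,
                        postOnsetEfficiencySlope = -0.02,
                        efficiencyNoiseSd = noise,
                        siteSdEfficiency = 0, geneSdEfficiency = 0)
    mean(sapply(1:20, function(s) {
      cfg@seed <- as.integer(100 * nMult + s)
      abs(bpSimOnce(cfg)@slopeChange + 0.02)
    }))
  }
  b <- c(bias(1, 0.04), bias(4, 0.01))
  expect_lt(b[2], b[1])
})

test_that("hub-gap interaction is antisymmetric in the group ordering", {
  ch <- generateCohort(hubSimConfig(7, 0.7), detail = "covariance")
  reg <- regionalTableFromCohort(ch)
  a <- suppressWarnings(hubGapInteraction(reg, c("carrier", "ftd")))
  b <- suppressWarnings(hubGapInteraction(reg, c("ftd", "carrier")))
  expect_equal(a@estimate, -b@estimate, tolerance = 1e-6)
  reg$hub_flag <- FALSE
  expect_error(hubGapInteraction(reg), "hub identification")
})

test_that("associations recover exact and absent relationships", {
  cfg <- cohortConfig(nGeneNegative = 0L, seed = 8)
  ch <- generateCohort(cfg, detail = "metadata")
  tbl <- analysisTable(ch$subjects,
                       ch$groundTruth$perSubject[, c("subject_id",
                                                     "true_strength")])
  tbl$copy <- tbl$true_strength
  ar <- suppressWarnings(associationByGroup(tbl, "true_strength", "copy"))
  expect_equal(unname(ar@r), c(1, 1))
  # independent x and y
  set.seed(9)
  tbl$noise <- rnorm(nrow(tbl))
  ar2 <- associationByGroup(tbl, "true_strength", "noise")
  expect_lt(abs(ar2@r[["carrier"]]), 0.2)
  # zero variance flagged, not errored
  tbl$flat <- 1
  ar3 <- associationByGroup(tbl, "flat", "noise")
  expect_true(is.na(ar3@r[["carrier"]]))
  expect_match(ar3@note, "zero variance")
})
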