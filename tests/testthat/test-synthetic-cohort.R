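# Synthetic cohort generator: sizes, determinism, imposed effects.

smallCfg <- function(seed = 3, ...) {
  cohortConfig(nGeneNegative = 10L, nCarrier = 8L, nFtd = 6L,
               nRegions = 24L, nTimepoints = 64L, seed = seed, ...)
}

test_that("group sizes add up and the subject table is well-formed", {
  ch <- generateCohort(cohortConfig(seed = 1), detail = "metadata")
  s <- ch$subjects
  expect_equal(nrow(s), 172)
  expect_equal(as.integer(table(s$group)[c("gene_negative", "carrier",
                                           "ftd")]),
               c(80L, 68L, 24L))
  expect_false(any(duplicated(s$subject_id)))
  expect_true(all(s$spike_pct >= 0 & s$spike_pct <= 100))
  expect_true(all(s$brain_volume_pct > 0 & s$brain_volume_pct < 100))
  expect_true(all(nchar(s$gene) > 0))      # every family has a gene label
  # sign convention: negative years = before expected onset
  yrs <- s$years_to_expected_onset
  expect_true(all(yrs[s$group == "carrier"] < 0))
  expect_true(all(yrs[s$group == "ftd"] >= 0))
  expect_true(all(c("mmse", "trails_a") %in% names(s)))
})

test_that("identical config and seed reproduce the cohort field for field", {
  a <- generateCohort(smallCfg(), detail = "timeseries")
  b <- generateCohort(smallCfg(), detail = "timeseries")
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$groundTruth$perSubject, b$groundTruth$perSubject)
  expect_identical(lapply(a$timeseries, signalMatrix),
                   lapply(b$timeseries, signalMatrix))
  d <- generateCohort(smallCfg(seed = 4), detail = "metadata")
  expect_false(identical(a$subjects$age, d$subjects$age))
})

test_that("with all effects null the groups share the same mean correlation", {
  nullCfg <- function(seed) {
    cohortConfig(nGeneNegative = 12L, nCarrier = 12L, nFtd = 8L,
                 nRegions = 30L, seed = seed,
                 ftdStrengthScale = 1, strengthOnsetSlope = 0,
                 carrierEfficiencyOffset = 0, preOnsetEfficiencySlope = 0,
                 postOnsetEfficiencySlope = 0, ftdStrengthSpread = 0)
  }
  means <- t(sapply(1:20, function(s) {
    ps <- generateCohort(nullCfg(s), detail = "covariance")$groundTruth$perSubject
    tapply(ps$true_mean_offdiag, ps$group, mean)
  }))
  grand <- colMeans(means)
  # Monte-Carlo error of a group mean over 20 cohorts is well under 2%
  expect_lt(max(grand) / min(grand) - 1, 0.02)
})

test_that("decreasing ftd_strength_scale decreases FTD connectivity", {
  ftdMean <- function(scale) {
    mean(sapply(1:5, function(s) {
      cfg <- cohortConfig(nGeneNegative = 4L, nCarrier = 4L, nFtd = 10L,
                          nRegions = 30L, seed = s,
                          ftdStrengthScale = scale, strengthOnsetSlope = 0,
                          ftdStrengthSpread = 0)
      ps <- generateCohort(cfg, detail = "covariance")$groundTruth$perSubject
      mean(ps$true_mean_offdiag[ps$group == "ftd"])
    }))
  }
  m <- vapply(c(1, 0.8, 0.6), ftdMean, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("simulateBold reproduces degenerate correlation structures", {
  band <- selectWaveletScale(2.2)
  # two regions driven by one identical latent row -> wavelet corr ~ 1
  cv <- matrix(1, 2, 2)
  ts <- simulateBold(cv, 256, 2.2, band, seed = 8)
  expect_gte(connValues(waveletCorrelationMatrix(ts, band))[1, 2], 0.99)
  expect_error(simulateBold(matrix(c(1, 2, 2, 1), 2), 64, 2.2, band),
               "positive semi-definite")
})

test_that("spike percentages exercise the exclusion stage at a realistic rate", {
  ch <- generateCohort(cohortConfig(nGeneNegative = 400L, nCarrier = 0L,
                                    nFtd = 0L, seed = 2),
                       detail = "metadata")
  rate <- mean(ch$subjects$spike_pct > 10)
  # design rate is 0.9^25.2 = 7.0%; binomial tolerance at n = 400
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.13)
})
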