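# Spike-percentage QC, wavelet scale selection, MODWT correlation.

test_that("exclusion uses a strict 10% boundary and partitions exhaustively", {
  subs <- data.frame(subject_id = c("a", "b", "c", "d"),
                     spike_pct = c(10.1, 9.9, 10.0, 0))
  ex <- excludeBySpikePct(subs)
  expect_equal(ex$excluded$subject_id, "a")      # 10.1 out
  expect_true(all(c("b", "c", "d") %in% ex$retained$subject_id))  # 10.0 stays
  expect_equal(nrow(ex$retained) + nrow(ex$excluded), nrow(subs))
  allZero <- data.frame(subject_id = letters[1:5], spike_pct = rep(0, 5))
  expect_equal(nrow(excludeBySpikePct(allZero)$excluded), 0)
  bad <- data.frame(subject_id = c("x", "y"), spike_pct = c(2, NA))
  expect_error(excludeBySpikePct(bad), "y")
})

test_that("a 185-subject cohort with 13 high-motion subjects retains 172", {
  # deterministic fixture mirroring the emulated study's QC outcome
  spikes <- rep(2, 185)
  spikes[seq(7, by = 14, length.out = 13)] <- 10 + seq_len(13)
  subs <- data.frame(subject_id = sprintf("S%03d", 1:185),
                     spike_pct = spikes)
  ex <- excludeBySpikePct(subs, 10)
  expect_equal(nrow(ex$excluded), 13)
  expect_equal(nrow(ex$retained), 172)
})

test_that("wavelet scale selection maximizes overlap with the target band", {
  b <- selectWaveletScale(2.0)
  expect_equal(b@scaleIndex, 2L)
  expect_equal(b@fLow, 0.0625)
  expect_equal(b@fHigh, 0.125)
  b2 <- selectWaveletScale(2.2)
  expect_equal(b2@scaleIndex, 2L)
  # independent enumeration of the dyadic overlaps at TR 2.2
  fs <- 1 / 2.2
  ov <- sapply(1:6, function(j) {
    max(0, min(fs / 2^j, 0.125) - max(fs / 2^(j + 1), 0.0675))
  })
  expect_equal(ov[2], 0.0461, tolerance = 1e-2)
  expect_equal(ov[1], 0.0114, tolerance = 1e-2)
  expect_equal(which.max(ov), 2L)
  expect_error(selectWaveletScale(2.2, c(0.3, 0.4)), "Nyquist")
})

test_that("MODWT coefficients match a naive direct-convolution oracle", {
  set.seed(7)
  x <- rnorm(128)
  for (j in 1:3) {
    expect_equal(modwtCoefficients(x, j), naiveModwtOracle(x, j),
                 tolerance = 1e-12)
  }
  expect_error(modwtCoefficients(rnorm(6), 2), "too short")
})

test_that("wavelet correlation has exact identity, antisymmetry and scale invariance", {
  band <- selectWaveletScale(2.2)
  ts <- simulateBold(diag(3), 256, 2.2, band, seed = 4)
  sig <- signalMatrix(ts)
  sig[2, ] <- -sig[1, ]
  tsx <- new("ParcellatedTimeSeries", subjectId = "x", signal = sig,
             trSeconds = 2.2)
  v <- connValues(waveletCorrelationMatrix(tsx, band))
  expect_equal(diag(v), rep(1, 3))
  expect_equal(v[1, 2], -1, tolerance = 1e-10)
  # global rescaling leaves the matrix unchanged
  tsy <- new("ParcellatedTimeSeries", subjectId = "y", signal = 100 * sig,
             trSeconds = 2.2)
  expect_equal(connValues(waveletCorrelationMatrix(tsy, band)), v,
               tolerance = 1e-12)
  # constant signal raises, naming the region
  sig[3, ] <- 5
  tsz <- new("ParcellatedTimeSeries", subjectId = "z", signal = sig,
             trSeconds = 2.2)
  expect_error(waveletCorrelationMatrix(tsz, band), "3")
})

test_that("wavelet correlation estimates converge to the target with T", {
  band <- selectWaveletScale(2.2)
  cv <- matrix(c(1, 0.5, 0.5, 1), 2)
  sds <- sapply(c(128, 512, 2048), function(T) {
    set.seed(20 + T)
    est <- replicate(40, {
      ts <- simulateBold(cv, T, 2.2, band, seed = sample.int(1e6, 1))
      connValues(waveletCorrelationMatrix(ts, band))[1, 2]
    })
    expect_lt(abs(mean(est) - 0.5), 4 * stats::sd(est) / sqrt(40) + 0.02)
    stats::sd(est)
  })
  expect_true(all(diff(sds) < 0))
})
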