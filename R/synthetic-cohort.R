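# Synthetic cohort generator: metadata, ground-truth covariances and
# BOLD-like signals for a three-group genetic FTD family study.

# Distance-decaying correlation kernel on a ring of nRegions positions.
# Local (lattice-like) structure at gMix = 0; fully distance-independent
# (random, topologically integrated) structure at gMix = 1.
ringKernel <- function(nRegions, localKernelScale) {
  pos <- (seq_len(nRegions) - 1) / nRegions
  d <- abs(outer(pos, pos, "-"))
  d <- pmin(d, 1 - d)                      # circular distance in [0, 0.5]
  exp(-d / localKernelScale)
}

# One subject's target correlation matrix. The subject's network state is
# summarized by two scalars: gamma (overall connectivity scale -> strength)
# and gMix (global-vs-local mixing -> topological efficiency). Hub rows are
# multiplicatively boosted; the matrix is renormalized so that the mean
# off-diagonal correlation equals baseCorrelation * gamma exactly, which
# decouples strength from topology by construction.
buildSubjectCovariance <- function(kernel, hubSet, gMix, gamma, config,
                                   hubScale = 1, project = TRUE) {
  n <- nrow(kernel)
  gMix <- min(max(gMix, 0.02), 0.95)
  m <- (1 - gMix) * kernel + gMix
  b <- rep(1, n)
  b[hubSet] <- sqrt(config@hubWeightBoost)
  m <- m * tcrossprod(b)
  if (hubScale != 1 && length(hubSet)) {
    isHub <- seq_len(n) %in% hubSet
    inc <- outer(isHub, isHub, "|")
    m[inc] <- m[inc] * hubScale
  }
  diag(m) <- 0
  meanOff <- sum(m) / (n * (n - 1))
  m <- m * (config@baseCorrelation * gamma / meanOff)
  if (config@covJitterSd > 0) {
    j <- matrix(stats::rnorm(n * n, sd = config@covJitterSd), n, n)
    m <- m + (j + t(j)) / sqrt(2)
    m <- (m + t(m)) / 2
  }
  m[m > 0.97] <- 0.97
  m[m < -0.97] <- -0.97
  diag(m) <- 1
  if (project) m <- nearestPsdCorrelation(m)
  # restore the exact target mean off-diagonal correlation (capping,
  # jitter and the PSD projection all perturb it slightly); shrinking
  # toward the identity preserves positive semi-definiteness, and the
  # rare s > 1 case is re-projected. This keeps connection strength
  # decoupled from the topology parameters by construction.
  target <- config@baseCorrelation * gamma
  cur <- sum(m[upper.tri(m)]) / (n * (n - 1) / 2)
  if (is.finite(cur) && cur > 1e-6) {
    s <- target / cur
    m <- s * m
    diag(m) <- 1
    if (s > 1 && project) {
      m[m > 0.97] <- 0.97
      m <- nearestPsdCorrelation(m)
    }
  }
  m
}

#' Generate a seeded synthetic genetic-FTD cohort
#'
#' Generates subject metadata (group, age, sex, site, family gene,
#' years-to-expected-onset, spike percentage, brain volume, cognitive
#' z-scores), per-subject ground-truth network state, and optionally
#' target correlation matrices and BOLD-like parcellated time series.
#' Expected onset age is drawn per family; `years_to_expected_onset` is
#' negative before expected onset. Carriers span -25 to -1 years before
#' onset, FTD patients 0 to +10 years after, gene-negative relatives -25
#' to +5 (the covariate exists for them but drives no effect).
#'
#' The generator imposes, through two per-subject scalars (connectivity
#' scale and topological-organization score): a continuous per-year
#' connectivity decline along years-to-onset in mutation carriers, an
#' optional FTD step deficit (`ftdStrengthScale`), a piecewise
#' organization trajectory with a breakpoint at expected onset, a
#' strength-volume coupling confined to the FTD group, and cognitive
#' scores loading on connection strength with an FTD impairment shift.
#'
#' @param config a [CohortConfig].
#' @param detail `"timeseries"` (full: matrices + BOLD signals),
#'   `"covariance"` (matrices and regional strengths, no signals), or
#'   `"metadata"` (fast: subject table and analytic ground truth only;
#'   used for large simulation studies).
#'
#' @return list with elements
#'   \describe{
#'     \item{subjects}{data.frame, one row per subject (the
#'       `subjects.tsv` layout).}
#'     \item{timeseries}{list of [ParcellatedTimeSeries] (or `NULL`).}
#'     \item{groundTruth}{list: `perSubject` data.frame (true network
#'       state, echoed imposed effects), `hubSet`, `covariances`,
#'       `regionalStrength` (subjects x regions analytic strengths),
#'       `config`.}
#'   }
#' @examples
#' cohort <- generateCohort(cohortConfig(nGeneNegative = 6, nCarrier = 6,
#'                                       nFtd = 4, nRegions = 20,
#'                                       nTimepoints = 64, seed = 3),
#'                          detail = "metadata")
#' head(cohort$subjects)
#' @export
generateCohort <- function(config,
                           detail = c("timeseries", "covariance",
                                      "metadata")) {
  detail <- match.arg(detail)
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  nTotal <- config@nGeneNegative + config@nCarrier + config@nFtd
  if (nTotal < 1L) stop("cohort is empty: all group counts are zero")
  band <- selectWaveletScale(config@trSeconds)

  withSeed(config@seed, {
    group <- factor(rep(c("gene_negative", "carrier", "ftd"),
                        times = c(config@nGeneNegative, config@nCarrier,
                                  config@nFtd)),
                    levels = c("gene_negative", "carrier", "ftd"))
    n <- length(group)
    subjectId <- sprintf("S%03d", seq_len(n))

    onsetAge <- stats::rnorm(n, config@familyOnsetMean, config@familyOnsetSd)
    years <- numeric(n)
    years[group == "gene_negative"] <-
      stats::runif(sum(group == "gene_negative"), -25, 5)
    years[group == "carrier"] <- stats::runif(sum(group == "carrier"), -25, -1)
    years[group == "ftd"] <- stats::runif(sum(group == "ftd"), 0, 10)
    age <- pmin(pmax(onsetAge + years, 21), 89)

    pMale <- c(gene_negative = 0.61, carrier = 0.59, ftd = 0.29)
    sex <- ifelse(stats::runif(n) < pMale[as.character(group)], "M", "F")
    site <- paste0("site", sample.int(config@nSites, n, replace = TRUE))
    geneProbs <- rep(1 / length(config@geneLabels),
                     length(config@geneLabels))
    gene <- sample(config@geneLabels, n, replace = TRUE, prob = geneProbs)

    sp <- config@spikePctDistribution
    spikePct <- pmin(sp$scale * stats::rbeta(n, sp$shape1, sp$shape2), 100)

    carrierLike <- group %in% c("carrier", "ftd")

    # site / gene random intercepts for the two analytic outcomes
    uSiteS <- stats::rnorm(config@nSites, 0, config@siteSdStrength)
    uSiteE <- stats::rnorm(config@nSites, 0, config@siteSdEfficiency)
    uGeneS <- stats::rnorm(length(config@geneLabels), 0,
                           config@geneSdStrength)
    uGeneE <- stats::rnorm(length(config@geneLabels), 0,
                           config@geneSdEfficiency)
    siteIdx <- as.integer(sub("site", "", site))
    geneIdx <- match(gene, config@geneLabels)

    # connectivity scale gamma: continuous years slope + FTD step +
    # subject noise + site/gene intercepts (expressed multiplicatively so
    # the covariance stays a valid correlation matrix)
    gammaYears <- ifelse(carrierLike,
                         1 + config@strengthOnsetSlope * years, 1)
    gammaStep <- ifelse(group == "ftd", config@ftdStrengthScale, 1)
    strengthLogSd <- ifelse(group == "ftd",
                            sqrt(config@subjectStrengthSd^2 +
                                   config@ftdStrengthSpread^2),
                            config@subjectStrengthSd)
    gamma <- gammaYears * gammaStep *
      exp(stats::rnorm(n, 0, strengthLogSd) +
            (uSiteS[siteIdx] + uGeneS[geneIdx]) / config@baselineStrength)
    gamma <- pmax(gamma, 0.05)
    trueStrength <- config@baselineStrength * gamma

    # topological organization score: piecewise-linear in years-to-onset
    effScore <- config@baselineEfficiency +
      ifelse(carrierLike,
             config@carrierEfficiencyOffset +
               config@preOnsetEfficiencySlope * pmin(years, 0) +
               config@postOnsetEfficiencySlope * pmax(years, 0),
             0) +
      stats::rnorm(n, 0, config@efficiencyNoiseSd) +
      uSiteE[siteIdx] + uGeneE[geneIdx]
    gMix <- config@globalMixBase +
      config@globalMixGain * (effScore - config@baselineEfficiency)

    # brain volume: aging decline; FTD shifted and coupled to strength
    volume <- config@volumeBase + config@volumeAgeSlope * (age - 50) +
      ifelse(group == "ftd", config@volumeFtdShift, 0)
    isFtd <- group == "ftd"
    if (sum(isFtd) >= 3 && stats::sd(trueStrength[isFtd]) > 0) {
      zs <- scale(trueStrength[isFtd])[, 1]
      r <- config@volumeCouplingR
      volume[isFtd] <- volume[isFtd] +
        config@volumeSd * (r * zs + sqrt(max(0, 1 - r^2)) *
                             stats::rnorm(sum(isFtd)))
    } else {
      volume[isFtd] <- volume[isFtd] +
        stats::rnorm(sum(isFtd), 0, config@volumeSd)
    }
    volume[!isFtd] <- volume[!isFtd] +
      stats::rnorm(sum(!isFtd), 0, config@volumeSd)
    volume <- pmin(pmax(volume, 40), 99)

    # cognitive z-scores load on standardized connection strength
    zAll <- if (stats::sd(trueStrength) > 0) scale(trueStrength)[, 1]
            else rep(0, n)
    cogScores <- lapply(names(config@cognitionCoupling), function(test) {
      config@cognitionCoupling[[test]] * zAll +
        ifelse(isFtd, config@ftdCognitionShift, 0) +
        stats::rnorm(n, 0, config@cognitionNoiseSd)
    })
    names(cogScores) <- names(config@cognitionCoupling)

    subjects <- data.frame(
      subject_id = subjectId, group = as.character(group), age = age,
      sex = sex, site = site, gene = gene,
      years_to_expected_onset = years, spike_pct = spikePct,
      brain_volume_pct = volume, stringsAsFactors = FALSE)
    for (test in names(cogScores)) subjects[[test]] <- cogScores[[test]]

    nHubs <- round(config@hubFraction * config@nRegions)
    hubSet <- if (nHubs >= 1) sort(sample.int(config@nRegions, nHubs))
              else integer(0)

    perSubject <- data.frame(
      subject_id = subjectId, group = as.character(group),
      true_strength = trueStrength, true_efficiency_score = effScore,
      gamma = gamma, g_mix = gMix,
      true_mean_offdiag = NA_real_,
      imposed_group_effect = ifelse(isFtd,
        -config@baselineStrength * (1 - config@ftdStrengthScale), 0),
      imposed_pre_slope = config@preOnsetEfficiencySlope,
      imposed_post_slope = config@postOnsetEfficiencySlope,
      stringsAsFactors = FALSE)

    covariances <- NULL
    regionalStrength <- NULL
    timeseries <- NULL
    if (detail %in% c("covariance", "timeseries")) {
      kernel <- ringKernel(config@nRegions, config@localKernelScale)
      covariances <- vector("list", n)
      regionalStrength <- matrix(NA_real_, n, config@nRegions,
                                 dimnames = list(subjectId, NULL))
      hubScales <- ifelse(isFtd, config@ftdHubScale, 1)
      for (i in seq_len(n)) {
        cv <- buildSubjectCovariance(kernel, hubSet, gMix[i], gamma[i],
                                     config, hubScale = hubScales[i])
        covariances[[i]] <- cv
        perSubject$true_mean_offdiag[i] <-
          sum(cv[upper.tri(cv)]) / (config@nRegions *
                                      (config@nRegions - 1) / 2)
        regionalStrength[i, ] <- (rowSums(cv) - 1) +
          stats::rnorm(config@nRegions, 0, config@regionalNoiseSd)
      }
      names(covariances) <- subjectId
      if (detail == "timeseries") {
        timeseries <- vector("list", n)
        for (i in seq_len(n)) {
          timeseries[[i]] <- simulateBold(
            covariances[[i]], config@nTimepoints, config@trSeconds, band,
            seed = deriveSeed(config@seed, i),
            noiseSd = config@noiseSd, subjectId = subjectId[i])
        }
        names(timeseries) <- subjectId
      }
    }

    list(subjects = subjects, timeseries = timeseries,
         groundTruth = list(perSubject = perSubject, hubSet = hubSet,
                            covariances = covariances,
                            regionalStrength = regionalStrength,
                            config = config))
  })
}

#' Simulate band-limited BOLD-like signals with a target correlation
#' structure
#'
#' Draws temporally white multivariate Gaussian innovations with the given
#' spatial covariance and bandpass-filters them into the analysis band
#' (order-2 Butterworth, zero-phase). Because every region passes through
#' the identical linear filter, the wavelet-scale cross-correlations of
#' the output converge to the correlations of `covariance` as the series
#' lengthens; a small white measurement-noise floor (`noiseSd`) is added
#' on top.
#'
#' @param covariance symmetric positive semi-definite region x region
#'   matrix (a correlation matrix in typical use).
#' @param nTimepoints number of time points to simulate.
#' @param trSeconds sampling interval in seconds.
#' @param band a [WaveletBand] from [selectWaveletScale()].
#' @param seed integer seed.
#' @param noiseSd sd of added white measurement noise (unit signal scale).
#' @param subjectId identifier stored in the result.
#'
#' @return a [ParcellatedTimeSeries].
#' @examples
#' band <- selectWaveletScale(2.0)
#' ts <- simulateBold(diag(4), 128, 2.0, band, seed = 1)
#' dim(signalMatrix(ts))
#' @export
simulateBold <- function(covariance, nTimepoints, trSeconds, band,
                         seed = 1L, noiseSd = 0, subjectId = "sim") {
  if (!isSymmetricMatrix(covariance, tol = 1e-6))
    stop("covariance must be a symmetric matrix")
  e <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("covariance is not positive semi-definite")
  vals <- pmax(e$values, 0)
  l <- e$vectors %*% diag(sqrt(vals), nrow = length(vals))
  nR <- nrow(covariance)
  withSeed(seed, {
    z <- matrix(stats::rnorm(nTimepoints * nR), nTimepoints, nR)
    x <- z %*% t(l)                       # time x regions, cov = covariance
    nyq <- 1 / (2 * trSeconds)
    wl <- max(band@fLow / nyq, 1e-3)
    wh <- min(band@fHigh / nyq, 1 - 1e-3)
    if (wl < wh) {
      bf <- signal::butter(2, c(wl, wh), type = "pass")
      x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
    }
    if (noiseSd > 0) {
      sref <- stats::sd(as.vector(x))
      x <- x + matrix(stats::rnorm(nTimepoints * nR,
                                   sd = noiseSd * max(sref, 1e-12)),
                      nTimepoints, nR)
    }
    new("ParcellatedTimeSeries", subjectId = subjectId, signal = t(x),
        trSeconds = trSeconds)
  })
}
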