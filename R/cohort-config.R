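#' Synthetic cohort configuration
#'
#' Holds every parameter of the synthetic multi-site genetic FTD family
#' cohort: group sizes, acquisition geometry, the hub-structured
#' correlation model, the group/onset effect sizes, and the couplings of
#' network state to brain volume and cognition. Identical configuration +
#' seed always reproduces the identical cohort.
#'
#' Defaults are the emulated study conditions: 80 gene-negative relatives,
#' 68 presymptomatic carriers, 24 symptomatic FTD patients; TR 2.2 s
#' acquisitions of about 315 s; 500-region parcellations (desk-scale demos
#' use [demoRunConfig()] which reduces regions, time points and null
#' counts). See the methods vignette for the rationale behind every effect
#' size.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nGeneNegative = "integer", nCarrier = "integer", nFtd = "integer",
    nRegions = "integer", nTimepoints = "integer", trSeconds = "numeric",
    nSites = "integer", geneLabels = "character", seed = "integer",
    hubFraction = "numeric", hubWeightBoost = "numeric",
    ftdStrengthScale = "numeric", ftdHubScale = "numeric",
    strengthOnsetSlope = "numeric",
    carrierEfficiencyOffset = "numeric",
    preOnsetEfficiencySlope = "numeric",
    postOnsetEfficiencySlope = "numeric",
    volumeCouplingR = "numeric", cognitionCoupling = "list",
    noiseSd = "numeric", spikePctDistribution = "list",
    baseCorrelation = "numeric", localKernelScale = "numeric",
    globalMixBase = "numeric", globalMixGain = "numeric",
    covJitterSd = "numeric", subjectStrengthSd = "numeric",
    ftdStrengthSpread = "numeric",
    efficiencyNoiseSd = "numeric", regionalNoiseSd = "numeric",
    siteSdStrength = "numeric", geneSdStrength = "numeric",
    siteSdEfficiency = "numeric", geneSdEfficiency = "numeric",
    baselineStrength = "numeric", baselineEfficiency = "numeric",
    familyOnsetMean = "numeric", familyOnsetSd = "numeric",
    ftdCognitionShift = "numeric", cognitionNoiseSd = "numeric",
    volumeBase = "numeric", volumeSd = "numeric", volumeFtdShift = "numeric",
    volumeAgeSlope = "numeric"),
  validity = function(object) {
    msg <- character()
    chkCount <- function(x, nm) {
      if (length(x) != 1L || is.na(x) || x < 0L)
        msg <<- c(msg, sprintf("%s must be a non-negative count", nm))
    }
    chkCount(object@nGeneNegative, "n_gene_negative")
    chkCount(object@nCarrier, "n_carrier")
    chkCount(object@nFtd, "n_ftd")
    if (object@nRegions < 2L) msg <- c(msg, "n_regions must be >= 2")
    if (object@nTimepoints < 8L) msg <- c(msg, "n_timepoints must be >= 8")
    if (length(object@trSeconds) != 1L || is.na(object@trSeconds) ||
        object@trSeconds <= 0)
      msg <- c(msg, "tr_seconds (trSeconds) must be a positive number")
    if (is.na(object@hubFraction) || object@hubFraction < 0 ||
        object@hubFraction > 1)
      msg <- c(msg, "hub_fraction must lie in [0, 1]")
    if (object@hubWeightBoost < 1) msg <- c(msg, "hub_weight_boost must be >= 1")
    if (is.na(object@ftdStrengthScale) || object@ftdStrengthScale <= 0 ||
        object@ftdStrengthScale > 1)
      msg <- c(msg, "ftd_strength_scale must lie in (0, 1]")
    if (object@ftdHubScale <= 0) msg <- c(msg, "ftd_hub_scale must be positive")
    if (object@baseCorrelation <= 0 || object@baseCorrelation >= 1)
      msg <- c(msg, "base_correlation must lie in (0, 1)")
    if (object@noiseSd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (!all(c("shape1", "shape2", "scale") %in%
             names(object@spikePctDistribution)))
      msg <- c(msg, "spike_pct_distribution needs shape1, shape2, scale")
    if (length(object@geneLabels) < 1L) msg <- c(msg, "gene_labels must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' Create a synthetic cohort configuration
#'
#' All arguments have study-condition defaults; see [CohortConfig] and the
#' methods vignette. Effect-size parameters:
#' `strengthOnsetSlope` is the per-year relative decline in mean
#' connectivity along years-to-expected-onset (carriers and FTD);
#' `ftdStrengthScale` is an additional multiplicative step on FTD
#' off-diagonal correlations (default 1, i.e. no step: the deficit is
#' carried by the continuous slope); `preOnsetEfficiencySlope` /
#' `postOnsetEfficiencySlope` are the piecewise per-year slopes of the
#' network-organization score before/after expected onset;
#' `carrierEfficiencyOffset` lifts mutation carriers' organization score;
#' `volumeCouplingR` is the target strength-volume correlation inside the
#' FTD group; `cognitionCoupling` maps test name to its loading on
#' standardized connection strength.
#'
#' @param nGeneNegative,nCarrier,nFtd group sizes (default 80/68/24).
#' @param nRegions number of parcellated regions.
#' @param nTimepoints number of fMRI volumes.
#' @param trSeconds repetition time in seconds.
#' @param nSites number of acquisition sites.
#' @param geneLabels family gene labels.
#' @param seed integer RNG seed; same config + seed gives an identical
#'   cohort.
#' @param hubFraction proportion of regions designated hubs.
#' @param hubWeightBoost multiplicative connectivity boost on hub regions
#'   (>= 1).
#' @param ftdStrengthScale multiplier in (0, 1] on FTD off-diagonal
#'   correlations.
#' @param ftdHubScale multiplier on FTD hub-incident correlations (1 = no
#'   hub-specific weakening).
#' @param strengthOnsetSlope relative connectivity change per year of
#'   years-to-expected-onset in carriers/FTD.
#' @param carrierEfficiencyOffset organization-score offset for mutation
#'   carriers (incl. FTD).
#' @param preOnsetEfficiencySlope,postOnsetEfficiencySlope signed per-year
#'   slopes of the organization score before/after expected onset.
#' @param volumeCouplingR target Pearson correlation between connection
#'   strength and brain volume inside the FTD group.
#' @param cognitionCoupling named list, test -> loading on standardized
#'   strength.
#' @param noiseSd white measurement noise added to the simulated BOLD
#'   signal (relative to unit signal amplitude).
#' @param spikePctDistribution list(shape1, shape2, scale): spike
#'   percentages are `scale * rbeta(shape1, shape2)`. The default
#'   Beta(1, 25.2) scaled to 100 gives P(spike > 10%) = 0.9^25.2 = 7.0%,
#'   the exclusion rate of the emulated study (13 of 185).
#' @param baseCorrelation mean off-diagonal correlation at baseline.
#' @param localKernelScale e-folding distance (fraction of the ring) of
#'   the distance-decaying local correlation kernel.
#' @param globalMixBase,globalMixGain map the organization score onto the
#'   global (distance-independent) mixing proportion of the kernel.
#' @param covJitterSd entrywise sd of the symmetric jitter added to each
#'   subject's correlation matrix.
#' @param subjectStrengthSd sd of the per-subject log-normal connectivity
#'   scale factor.
#' @param ftdStrengthSpread additional log-normal connectivity spread in
#'   the FTD group (clinical heterogeneity of the symptomatic stage).
#' @param efficiencyNoiseSd per-subject sd of the organization score.
#' @param regionalNoiseSd per-region sd of analytic regional strengths.
#' @param siteSdStrength,geneSdStrength,siteSdEfficiency,geneSdEfficiency
#'   sds of the site and gene random intercepts on the two outcomes.
#' @param baselineStrength analytic connection-strength unit (arbitrary).
#' @param baselineEfficiency baseline organization score.
#' @param familyOnsetMean,familyOnsetSd distribution of per-family
#'   expected symptom onset ages (years).
#' @param ftdCognitionShift additive z-score shift of FTD cognitive
#'   scores.
#' @param cognitionNoiseSd residual sd of cognitive z-scores.
#' @param volumeBase,volumeSd,volumeFtdShift,volumeAgeSlope brain volume
#'   (% of total intracranial volume) model: base level, residual sd, FTD
#'   shift, per-year age slope.
#'
#' @return a validated [CohortConfig] object.
#' @examples
#' cfg <- cohortConfig(nRegions = 40, nTimepoints = 128, seed = 7)
#' cfg
#' @export
cohortConfig <- function(nGeneNegative = 80L, nCarrier = 68L, nFtd = 24L,
                         nRegions = 500L, nTimepoints = 144L,
                         trSeconds = 2.2, nSites = 4L,
                         geneLabels = c("C9orf72", "MAPT", "GRN"),
                         seed = 1L,
                         hubFraction = 0.12, hubWeightBoost = 1.5,
                         ftdStrengthScale = 1.0, ftdHubScale = 1.0,
                         strengthOnsetSlope = -0.01,
                         carrierEfficiencyOffset = 0.03,
                         preOnsetEfficiencySlope = 0.0015,
                         postOnsetEfficiencySlope = -0.004,
                         volumeCouplingR = 0.8,
                         cognitionCoupling = list(
                           mmse = 0.35, trails_a = 0.35,
                           digit_span_forward = 0.25,
                           verbal_fluency_letter = 0.25),
                         noiseSd = 0.1,
                         spikePctDistribution = list(
                           shape1 = 1, shape2 = 25.2, scale = 100),
                         baseCorrelation = 0.22, localKernelScale = 0.1,
                         globalMixBase = 0.3, globalMixGain = 3,
                         covJitterSd = 0.02, subjectStrengthSd = 0.04,
                         ftdStrengthSpread = 0.12,
                         efficiencyNoiseSd = 0.012, regionalNoiseSd = 1,
                         siteSdStrength = 2, geneSdStrength = 1.5,
                         siteSdEfficiency = 0.004,
                         geneSdEfficiency = 0.003,
                         baselineStrength = 100, baselineEfficiency = 0.86,
                         familyOnsetMean = 58, familyOnsetSd = 7,
                         ftdCognitionShift = -2, cognitionNoiseSd = 0.9,
                         volumeBase = 82, volumeSd = 3, volumeFtdShift = -4,
                         volumeAgeSlope = -0.06) {
  new("CohortConfig",
      nGeneNegative = as.integer(nGeneNegative),
      nCarrier = as.integer(nCarrier), nFtd = as.integer(nFtd),
      nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints),
      trSeconds = as.numeric(trSeconds), nSites = as.integer(nSites),
      geneLabels = as.character(geneLabels), seed = as.integer(seed),
      hubFraction = hubFraction, hubWeightBoost = hubWeightBoost,
      ftdStrengthScale = ftdStrengthScale, ftdHubScale = ftdHubScale,
      strengthOnsetSlope = strengthOnsetSlope,
      carrierEfficiencyOffset = carrierEfficiencyOffset,
      preOnsetEfficiencySlope = preOnsetEfficiencySlope,
      postOnsetEfficiencySlope = postOnsetEfficiencySlope,
      volumeCouplingR = volumeCouplingR,
      cognitionCoupling = cognitionCoupling, noiseSd = noiseSd,
      spikePctDistribution = spikePctDistribution,
      baseCorrelation = baseCorrelation,
      localKernelScale = localKernelScale,
      globalMixBase = globalMixBase, globalMixGain = globalMixGain,
      covJitterSd = covJitterSd, subjectStrengthSd = subjectStrengthSd,
      ftdStrengthSpread = ftdStrengthSpread,
      efficiencyNoiseSd = efficiencyNoiseSd,
      regionalNoiseSd = regionalNoiseSd,
      siteSdStrength = siteSdStrength, geneSdStrength = geneSdStrength,
      siteSdEfficiency = siteSdEfficiency,
      geneSdEfficiency = geneSdEfficiency,
      baselineStrength = baselineStrength,
      baselineEfficiency = baselineEfficiency,
      familyOnsetMean = familyOnsetMean, familyOnsetSd = familyOnsetSd,
      ftdCognitionShift = ftdCognitionShift,
      cognitionNoiseSd = cognitionNoiseSd,
      volumeBase = volumeBase, volumeSd = volumeSd,
      volumeFtdShift = volumeFtdShift, volumeAgeSlope = volumeAgeSlope)
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: ", object@nGeneNegative, " gene-negative / ",
      object@nCarrier, " carrier / ", object@nFtd, " FTD subjects\n",
      "  ", object@nRegions, " regions x ", object@nTimepoints,
      " time points (TR ", object@trSeconds, " s), ", object@nSites,
      " sites, genes: ", paste(object@geneLabels, collapse = "/"),
      "\n  seed ", object@seed, "\n", sep = "")
})
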