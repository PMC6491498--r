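#' @import methods
NULL

#' Parcellated regional time series
#'
#' One subject's region-by-time signal matrix together with its sampling
#' interval. Rows are parcellated brain regions, columns are time points
#' (arbitrary signal units, e.g. preprocessed BOLD).
#'
#' @slot subjectId single subject identifier.
#' @slot signal numeric matrix, regions x time; all values finite.
#' @slot trSeconds sampling interval (repetition time) in seconds.
#'
#' @seealso [simulateBold()], [waveletCorrelationMatrix()]
#' @exportClass ParcellatedTimeSeries
setClass("ParcellatedTimeSeries",
  representation(subjectId = "character", signal = "matrix",
                 trSeconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
    if (!is.numeric(object@signal) || !all(is.finite(object@signal)))
      msg <- c(msg, "signal must be a finite numeric matrix")
    if (ncol(object@signal) < 2L) msg <- c(msg, "signal needs at least 2 time points")
    if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
        object@trSeconds <= 0)
      msg <- c(msg, "trSeconds (tr_seconds) must be a positive number")
    if (length(msg)) msg else TRUE
  })

#' Dyadic wavelet frequency band
#'
#' A wavelet scale and the dyadic frequency band it covers. For sampling
#' frequency fs = 1/TR, scale j covers fs/2^(j+1) to fs/2^j Hz.
#'
#' @slot scaleIndex integer wavelet scale (>= 1).
#' @slot fLow,fHigh band edges in Hz.
#' @slot waveletFamily filter family name (currently `"d4"`, Daubechies-4).
#'
#' @seealso [selectWaveletScale()]
#' @exportClass WaveletBand
setClass("WaveletBand",
  representation(scaleIndex = "integer", fLow = "numeric", fHigh = "numeric",
                 waveletFamily = "character"),
  validity = function(object) {
    msg <- character()
    if (object@scaleIndex < 1L) msg <- c(msg, "scaleIndex must be >= 1")
    if (!(object@fLow > 0 && object@fLow < object@fHigh))
      msg <- c(msg, "band must satisfy 0 < fLow < fHigh")
    if (length(msg)) msg else TRUE
  })

#' Wavelet cross-correlation connectivity matrix
#'
#' Symmetric region-by-region matrix of Pearson correlations between
#' wavelet coefficients at one dyadic scale; unit diagonal, entries in
#' \[-1, 1\].
#'
#' @slot subjectId subject identifier.
#' @slot values symmetric numeric matrix with unit diagonal.
#'
#' @seealso [waveletCorrelationMatrix()], [buildGraph()]
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(subjectId = "character", values = "matrix"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (!isSymmetricMatrix(v, tol = 1e-6)) msg <- c(msg, "values must be a symmetric square matrix")
    else {
      if (max(abs(diag(v) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
      if (min(v) < -1 - 1e-8 || max(v) > 1 + 1e-8) msg <- c(msg, "entries must lie in [-1, 1]")
    }
    if (!all(is.finite(v))) msg <- c(msg, "entries must be finite")
    if (length(msg)) msg else TRUE
  })

#' Thresholded weighted brain graph
#'
#' Undirected weighted graph over parcellated regions: a symmetric
#' non-negative weight matrix with zero diagonal, connected by
#' construction (maximum-spanning-tree backbone plus the strongest
#' remaining edges up to a target density).
#'
#' @slot subjectId subject identifier.
#' @slot weights symmetric non-negative matrix, zero diagonal.
#' @slot edgeDensity realized proportion of possible edges present.
#' @slot negativePolicy how negative correlations were handled
#'   (`"zero"` or `"absolute"`).
#' @slot targetDensity requested edge density.
#'
#' @seealso [buildGraph()], [computeNodalMetrics()], [computeGlobalMetrics()]
#' @exportClass BrainGraph
setClass("BrainGraph",
  representation(subjectId = "character", weights = "matrix",
                 edgeDensity = "numeric", negativePolicy = "character",
                 targetDensity = "numeric"),
  validity = function(object) {
    w <- object@weights
    msg <- character()
    if (!isSymmetricMatrix(w, tol = 1e-8)) msg <- c(msg, "weights must be symmetric")
    else {
      if (any(diag(w) != 0)) msg <- c(msg, "no self-edges allowed")
      if (min(w) < 0) msg <- c(msg, "weights must be non-negative")
      if (!adjacencyConnected(w)) msg <- c(msg, "graph must be connected")
    }
    if (length(msg)) msg else TRUE
  })

#' Specification of a degree-preserving null ensemble
#'
#' @slot nNulls number of null graphs (study default 500).
#' @slot swapsPerEdge degree-preserving edge swaps attempted per edge.
#' @slot seed integer RNG seed for the ensemble.
#'
#' @seealso [generateNullEnsemble()]
#' @exportClass NullEnsembleSpec
setClass("NullEnsembleSpec",
  representation(nNulls = "integer", swapsPerEdge = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nNulls < 1L) msg <- c(msg, "nNulls must be >= 1")
    if (object@swapsPerEdge < 1L) msg <- c(msg, "swapsPerEdge must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Global network metrics with null-model normalization
#'
#' @slot subjectId subject identifier.
#' @slot connectionStrengthTotal sum of nodal strengths (= 2 x sum of edge
#'   weights).
#' @slot globalEfficiencyRaw mean over ordered node pairs of inverse
#'   shortest-path length (distance = 1/weight).
#' @slot globalEfficiencyNormalized raw efficiency divided by the mean over
#'   the null ensemble (NA when no nulls were supplied).
#' @slot closenessNormalized per-node farness divided by its null-ensemble
#'   mean (degree-preserving nulls keep node identity meaningful).
#' @slot nNulls number of null graphs used.
#'
#' @seealso [computeGlobalMetrics()]
#' @exportClass GlobalMetrics
setClass("GlobalMetrics",
  representation(subjectId = "character", connectionStrengthTotal = "numeric",
                 globalEfficiencyRaw = "numeric",
                 globalEfficiencyNormalized = "numeric",
                 closenessNormalized = "numeric", nNulls = "integer"))

#' Result of a single fixed-effect contrast
#'
#' @slot label contrast label, e.g. `"ftd - carrier"`.
#' @slot estimate contrast estimate on the outcome scale.
#' @slot se standard error.
#' @slot df degrees of freedom (Satterthwaite for mixed fits, residual for
#'   ordinary least squares).
#' @slot statistic t statistic.
#' @slot p two-sided p value.
#' @slot method `"lmm"` or `"ols"`.
#' @slot note diagnostic notes (degenerate fits, dropped random factors).
#'
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(label = "character", estimate = "numeric", se = "numeric",
                 df = "numeric", statistic = "numeric", p = "numeric",
                 method = "character", note = "character"))

#' Result of a piecewise (breakpoint) regression at expected onset
#'
#' @slot preSlope slope per year before the knot.
#' @slot postSlope slope per year after the knot.
#' @slot slopeChange postSlope - preSlope.
#' @slot levelChange discontinuity at the knot.
#' @slot pBreakpoint joint test (F for OLS, likelihood ratio for mixed
#'   fits) of the slope-change and level-change terms.
#' @slot terms data.frame of per-term estimates, se and p values.
#' @slot n number of observations used.
#' @slot knot knot location in years from expected onset.
#' @slot method `"lmm"` or `"ols"`.
#'
#' @exportClass BreakpointResult
setClass("BreakpointResult",
  representation(preSlope = "numeric", postSlope = "numeric",
                 slopeChange = "numeric", levelChange = "numeric",
                 pBreakpoint = "numeric", terms = "data.frame", n = "integer",
                 knot = "numeric", method = "character"))

#' Per-group association with between-group interaction
#'
#' @slot groups the two groups compared.
#' @slot r per-group Pearson correlations (named).
#' @slot rP per-group correlation p values.
#' @slot nPerGroup per-group sample sizes.
#' @slot interactionEstimate slope difference between groups from
#'   `y ~ x * group + age`.
#' @slot interactionP p value of the interaction term.
#' @slot note diagnostic notes (degenerate groups).
#'
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(groups = "character", r = "numeric", rP = "numeric",
                 nPerGroup = "integer", interactionEstimate = "numeric",
                 interactionP = "numeric", note = "character"))
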