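# Accessors and show methods for the core containers.

#' @rdname ParcellatedTimeSeries-class
#' @param object,x a `ParcellatedTimeSeries` (or other container) instance.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname ParcellatedTimeSeries-class
#' @export
setMethod("subjectId", "ParcellatedTimeSeries", function(x) x@subjectId)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)

#' @rdname BrainGraph-class
#' @export
setMethod("subjectId", "BrainGraph", function(x) x@subjectId)

#' @rdname ParcellatedTimeSeries-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname ParcellatedTimeSeries-class
#' @export
setMethod("signalMatrix", "ParcellatedTimeSeries", function(x) x@signal)

#' @rdname ParcellatedTimeSeries-class
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname ParcellatedTimeSeries-class
#' @export
setMethod("trSeconds", "ParcellatedTimeSeries", function(x) x@trSeconds)

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname BrainGraph-class
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))

#' @rdname BrainGraph-class
#' @export
setMethod("graphWeights", "BrainGraph", function(x) x@weights)

#' @rdname BrainGraph-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname BrainGraph-class
#' @export
setMethod("nNodes", "BrainGraph", function(x) nrow(x@weights))

#' @rdname BrainGraph-class
#' @export
setGeneric("edgeDensity", function(x) standardGeneric("edgeDensity"))

#' @rdname BrainGraph-class
#' @export
setMethod("edgeDensity", "BrainGraph", function(x) x@edgeDensity)

setMethod("show", "ParcellatedTimeSeries", function(object) {
  cat("ParcellatedTimeSeries '", object@subjectId, "': ",
      nrow(object@signal), " regions x ", ncol(object@signal),
      " time points, TR = ", object@trSeconds, " s\n", sep = "")
})

setMethod("show", "WaveletBand", function(object) {
  cat("WaveletBand: scale ", object@scaleIndex, " (",
      signif(object@fLow, 4), "-", signif(object@fHigh, 4), " Hz, ",
      object@waveletFamily, ")\n", sep = "")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat("ConnectivityMatrix '", object@subjectId, "': ", nrow(v), " regions, ",
      "mean off-diagonal r = ", signif(mean(off), 4), "\n", sep = "")
})

setMethod("show", "BrainGraph", function(object) {
  w <- object@weights
  m <- sum(w[upper.tri(w)] > 0)
  cat("BrainGraph '", object@subjectId, "': ", nrow(w), " nodes, ", m,
      " edges (density ", signif(object@edgeDensity, 4), ", target ",
      object@targetDensity, ", negatives: ", object@negativePolicy, ")\n",
      sep = "")
})

setMethod("show", "GlobalMetrics", function(object) {
  cat("GlobalMetrics '", object@subjectId, "':\n",
      "  connection strength (total): ",
      signif(object@connectionStrengthTotal, 5), "\n",
      "  global efficiency raw: ", signif(object@globalEfficiencyRaw, 5),
      "\n  global efficiency normalized: ",
      signif(object@globalEfficiencyNormalized, 5),
      " (", object@nNulls, " nulls)\n", sep = "")
})

setMethod("show", "ContrastResult", function(object) {
  cat("ContrastResult [", object@method, "] ", object@label, ": estimate = ",
      signif(object@estimate, 4), " (se ", signif(object@se, 4), "), t(",
      signif(object@df, 4), ") = ", signif(object@statistic, 4), ", p = ",
      signif(object@p, 4), "\n", sep = "")
  if (nzchar(object@note)) cat("  note: ", object@note, "\n", sep = "")
})

setMethod("show", "BreakpointResult", function(object) {
  cat("BreakpointResult [", object@method, "] knot at ", object@knot,
      " years (n = ", object@n, "):\n",
      "  pre slope ", signif(object@preSlope, 4), "/yr, post slope ",
      signif(object@postSlope, 4), "/yr (change ",
      signif(object@slopeChange, 4), "), level change ",
      signif(object@levelChange, 4), "\n  joint breakpoint p = ",
      signif(object@pBreakpoint, 4), "\n", sep = "")
})

setMethod("show", "AssociationResult", function(object) {
  for (g in object@groups) {
    cat("  ", g, ": r = ", signif(object@r[[g]], 3), " (p = ",
        signif(object@rP[[g]], 3), ", n = ", object@nPerGroup[[g]], ")\n",
        sep = "")
  }
  cat("  interaction: ", signif(object@interactionEstimate, 4), " (p = ",
      signif(object@interactionP, 4), ")\n", sep = "")
})
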