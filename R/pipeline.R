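# End-to-end orchestration: simulate -> exclude -> connectivity ->
# graphs/metrics -> inference, with a manifest, run log and full config
# echo for auditability.

#' Pipeline run configuration
#'
#' @slot cohort a [CohortConfig].
#' @slot targetBand target frequency band (Hz) for scale selection.
#' @slot negativePolicy handling of negative correlations.
#' @slot targetDensity graph edge density.
#' @slot nullSpec a [NullEnsembleSpec] (per-subject seeds are derived
#'   deterministically from the cohort seed).
#' @slot spikeThresholdPct spike-percentage exclusion threshold.
#' @slot breakpointKnot breakpoint location (years from expected onset).
#' @slot alpha nominal significance level recorded in the report.
#' @slot outputDir output directory.
#' @slot logLevel `"info"` or `"quiet"`.
#' @slot writeTimeseries write per-subject time-series TSVs.
#'
#' @exportClass RunConfig
setClass("RunConfig",
  representation(cohort = "CohortConfig", targetBand = "numeric",
                 negativePolicy = "character", targetDensity = "numeric",
                 nullSpec = "NullEnsembleSpec",
                 spikeThresholdPct = "numeric", breakpointKnot = "numeric",
                 alpha = "numeric", outputDir = "character",
                 logLevel = "character", writeTimeseries = "logical"),
  validity = function(object) {
    msg <- character()
    v <- validObject(object@cohort, test = TRUE)
    if (!isTRUE(v)) msg <- c(msg, paste("cohort:", paste(v, collapse = "; ")))
    if (length(object@targetBand) != 2L ||
        !(object@targetBand[1] > 0 && object@targetBand[1] <
            object@targetBand[2]))
      msg <- c(msg, "target_band must be 0 < f_low < f_high")
    if (!object@negativePolicy %in% c("zero", "absolute"))
      msg <- c(msg, "negative_policy must be 'zero' or 'absolute'")
    if (!(object@targetDensity > 0 && object@targetDensity <= 1))
      msg <- c(msg, "target_density must lie in (0, 1]")
    if (!(object@spikeThresholdPct >= 0 && object@spikeThresholdPct <= 100))
      msg <- c(msg, "spike_threshold_pct must lie in [0, 100]")
    if (!(object@alpha > 0 && object@alpha < 1))
      msg <- c(msg, "alpha must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Pipeline run report
#'
#' @slot counts named integer vector: subjects generated, excluded,
#'   retained.
#' @slot manifest output files written (relative to `outputDir`).
#' @slot outputDir output directory used.
#' @slot seed cohort seed.
#' @slot band the selected [WaveletBand].
#' @slot hubSet identified hub region indices.
#' @slot results list of inference result objects (contrasts,
#'   breakpoints, hub interaction, associations).
#' @slot metrics per-subject global metrics table.
#' @slot multipleComparisonCorrection always `"none"`: network measures
#'   are not independent, so no correction is applied.
#'
#' @exportClass RunReport
setClass("RunReport",
  representation(counts = "integer", manifest = "character",
                 outputDir = "character", seed = "integer",
                 band = "WaveletBand", hubSet = "integer",
                 results = "list", metrics = "data.frame",
                 multipleComparisonCorrection = "character"))

setMethod("show", "RunReport", function(object) {
  cat("RunReport (seed ", object@seed, "):\n",
      "  subjects: ", object@counts[["generated"]], " generated, ",
      object@counts[["excluded"]], " excluded, ",
      object@counts[["retained"]], " retained\n",
      "  outputs in ", object@outputDir, ": ",
      paste(object@manifest, collapse = ", "), "\n",
      "  multiple-comparison correction: ",
      object@multipleComparisonCorrection, "\n", sep = "")
})

#' Create a pipeline run configuration
#'
#' Defaults mirror the emulated study: 10% spike threshold, target band
#' 0.0675-0.125 Hz, 2-SD hubs, 500-null normalization, negative
#' correlations zeroed, 10% edge density (exposed as a sensitivity
#' parameter). See [demoRunConfig()] for a desk-scale configuration.
#'
#' @param cohort a [CohortConfig].
#' @param targetBand target band in Hz.
#' @param negativePolicy `"zero"` or `"absolute"`.
#' @param targetDensity graph edge density in (0, 1].
#' @param nullSpec a [NullEnsembleSpec].
#' @param spikeThresholdPct exclusion threshold (percent).
#' @param breakpointKnot breakpoint knot (years from expected onset).
#' @param alpha nominal significance level (reporting only).
#' @param outputDir output directory.
#' @param logLevel `"info"` or `"quiet"`.
#' @param writeTimeseries also write per-subject time-series TSVs.
#' @return a validated [RunConfig].
#' @export
runConfig <- function(cohort = cohortConfig(),
                      targetBand = c(0.0675, 0.125),
                      negativePolicy = "zero", targetDensity = 0.1,
                      nullSpec = nullEnsembleSpec(),
                      spikeThresholdPct = 10, breakpointKnot = 0,
                      alpha = 0.05, outputDir = tempfile("resilnet_run_"),
                      logLevel = "info", writeTimeseries = FALSE) {
  new("RunConfig", cohort = cohort, targetBand = as.numeric(targetBand),
      negativePolicy = negativePolicy, targetDensity = targetDensity,
      nullSpec = nullSpec, spikeThresholdPct = spikeThresholdPct,
      breakpointKnot = breakpointKnot, alpha = alpha,
      outputDir = outputDir, logLevel = logLevel,
      writeTimeseries = writeTimeseries)
}

#' Desk-scale demo configuration
#'
#' The full study conditions (80/68/24 subjects, TR 2.2 s) at reduced
#' computational scale: 90 regions, 384 time points, 50 nulls. The
#' synthetic acquisitions are longer than the emulated study's median
#' scan so that single-subject wavelet-correlation estimator noise stays
#' workable at 90 regions (see the methods vignette). Runs end-to-end in
#' a few minutes on one CPU.
#'
#' @param seed cohort seed.
#' @param outputDir output directory.
#' @param ... overrides passed to [cohortConfig()]; they take precedence
#'   over the demo-scale defaults.
#' @return a [RunConfig].
#' @export
demoRunConfig <- function(seed = 1L, outputDir = tempfile("resilnet_run_"),
                          ...) {
  cohortArgs <- list(nRegions = 90L, nTimepoints = 384L, seed = seed)
  dots <- list(...)
  cohortArgs[names(dots)] <- dots
  runConfig(cohort = do.call(cohortConfig, cohortArgs),
            nullSpec = nullEnsembleSpec(nNulls = 50L,
                                        seed = deriveSeed(seed, 999L)),
            outputDir = outputDir)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> spike-percentage exclusion -> wavelet
#' connectivity -> thresholded graphs with null-normalized metrics ->
#' hub identification -> inference (group contrasts, onset breakpoints,
#' hub-by-group interaction, volume and cognition associations), writing
#' `subjects.tsv`, `connectivity/<id>.tsv`, `metrics.tsv`,
#' `nodal_metrics.tsv`, `contrasts.tsv`, `breakpoints.tsv`,
#' `associations.tsv` and `run.log` under the configured output
#' directory. Fully deterministic given the configuration seed.
#'
#' @param config a [RunConfig].
#' @return a [RunReport].
#' @examples
#' \donttest{
#' cfg <- demoRunConfig(seed = 1)
#' report <- runPipeline(cfg)
#' report
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  outDir <- config@outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("output_dir is not writable: ", outDir)
  logLines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    logLines <<- c(logLines, line)
    if (config@logLevel == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- character(0)

  note("config echo: seed=", config@cohort@seed,
       " groups=", config@cohort@nGeneNegative, "/",
       config@cohort@nCarrier, "/", config@cohort@nFtd,
       " regions=", config@cohort@nRegions,
       " T=", config@cohort@nTimepoints,
       " tr=", config@cohort@trSeconds,
       " band=", paste(config@targetBand, collapse = "-"),
       " density=", config@targetDensity,
       " nulls=", config@nullSpec@nNulls,
       " spike_threshold=", config@spikeThresholdPct,
       " negative_policy=", config@negativePolicy)
  note("model spec: outcome ~ group + age + (1|site) + (1|gene); ",
       "breakpoint: outcome ~ t + (t-knot)+ + 1[t>knot] + age; ",
       "hub gap: outcome ~ hub*group + age + (1|subject); ",
       "no multiple-comparison correction")

  cohort <- stage("simulate", generateCohort(config@cohort,
                                             detail = "timeseries"))
  subjects <- cohort$subjects
  note("simulate: ", nrow(subjects), " subjects, ",
       config@cohort@nRegions, " regions")
  writeTsv(subjects, file.path(outDir, "subjects.tsv"))
  manifest <- c(manifest, "subjects.tsv")
  gt <- cohort$groundTruth
  writeTsv(gt$perSubject, file.path(outDir, "ground_truth.tsv"))
  manifest <- c(manifest, "ground_truth.tsv")
  if (config@writeTimeseries) {
    tsDir <- file.path(outDir, "timeseries")
    dir.create(tsDir, showWarnings = FALSE)
    for (ts in cohort$timeseries) {
      m <- signalMatrix(ts)
      writeTsv(as.data.frame(t(m)), file.path(tsDir, paste0(
        subjectId(ts), ".tsv")))
    }
    manifest <- c(manifest, "timeseries/")
  }

  ex <- stage("exclude",
              excludeBySpikePct(subjects, config@spikeThresholdPct))
  retained <- ex$retained
  note("exclude: ", nrow(ex$excluded), " subjects above ",
       config@spikeThresholdPct, "% spikes removed, ", nrow(retained),
       " retained")
  if (nrow(retained) < 4L) stop("stage 'exclude' failed: too few ",
                                "subjects retained")

  band <- stage("connectivity",
                selectWaveletScale(config@cohort@trSeconds,
                                   config@targetBand))
  note("connectivity: wavelet scale ", band@scaleIndex, " (",
       signif(band@fLow, 4), "-", signif(band@fHigh, 4), " Hz)")
  connDir <- file.path(outDir, "connectivity")
  dir.create(connDir, showWarnings = FALSE)

  metricsRows <- vector("list", nrow(retained))
  nodalRows <- vector("list", nrow(retained))
  strengthByRegion <- matrix(NA_real_, nrow(retained),
                             config@cohort@nRegions)
  for (i in seq_len(nrow(retained))) {
    sid <- retained$subject_id[i]
    ts <- cohort$timeseries[[sid]]
    conn <- stage("connectivity", waveletCorrelationMatrix(ts, band))
    cm <- connValues(conn)
    colnames(cm) <- paste0("R", seq_len(ncol(cm)))
    writeTsv(as.data.frame(cm), file.path(connDir, paste0(sid, ".tsv")))
    # connection strength is a pure weight sum and needs no backbone:
    # it is computed on the full positive-weighted graph, while
    # path-length metrics (and their degree-preserving nulls, which are
    # undefined on a complete topology) use the density-thresholded graph
    fullGraph <- stage("metrics",
                       buildGraph(conn, config@negativePolicy, 1.0))
    graph <- stage("metrics",
                   buildGraph(conn, config@negativePolicy,
                              config@targetDensity))
    nulls <- stage("metrics", generateNullEnsemble(
      graph, nullEnsembleSpec(nNulls = config@nullSpec@nNulls,
                              swapsPerEdge = config@nullSpec@swapsPerEdge,
                              seed = deriveSeed(config@nullSpec@seed, i))))
    gm <- stage("metrics", computeGlobalMetrics(graph, nulls))
    nodal <- stage("metrics", computeNodalMetrics(graph))
    nodalStrength <- rowSums(graphWeights(fullGraph))
    strengthByRegion[i, ] <- nodalStrength
    metricsRows[[i]] <- data.frame(
      subject_id = sid,
      connection_strength_total = sum(nodalStrength),
      global_efficiency_raw = gm@globalEfficiencyRaw,
      global_efficiency_normalized = gm@globalEfficiencyNormalized)
    nodalRows[[i]] <- data.frame(
      subject_id = sid, node = nodal$node, strength = nodalStrength,
      farness = nodal$farness, nodal_efficiency = nodal$nodal_efficiency,
      closeness_normalized = gm@closenessNormalized)
  }
  metrics <- do.call(rbind, metricsRows)
  writeTsv(metrics, file.path(outDir, "metrics.tsv"))
  manifest <- c(manifest, "connectivity/", "metrics.tsv")
  note("metrics: ", nrow(metrics), " subjects x ",
       config@nullSpec@nNulls, " nulls")

  # hubs from the gene-negative group's mean regional strengths
  negIdx <- retained$group == "gene_negative"
  hubSet <- stage("metrics", identifyHubs(
    colMeans(strengthByRegion[negIdx, , drop = FALSE])))
  note("hubs: ", length(hubSet), " regions > mean + 2 SD in the ",
       "gene-negative group")
  nodalTable <- do.call(rbind, nodalRows)
  nodalTable$hub_flag <- nodalTable$node %in% hubSet
  writeTsv(nodalTable, file.path(outDir, "nodal_metrics.tsv"))
  manifest <- c(manifest, "nodal_metrics.tsv")

  tbl <- analysisTable(retained, metrics)
  outcomes <- c(strength = "connection_strength_total",
                efficiency = "global_efficiency_normalized")

  contrastRows <- list()
  results <- list(contrasts = list(), breakpoints = list(),
                  hubInteraction = NULL, associations = list())
  for (oc in names(outcomes)) {
    for (pair in list(c("ftd", "carrier"), c("carrier", "gene_negative"))) {
      cr <- stage("analyze", fitGroupContrast(tbl, outcomes[[oc]], pair))
      key <- paste0(oc, ": ", cr@label)
      results$contrasts[[key]] <- cr
      contrastRows[[key]] <- data.frame(
        outcome = oc, term = cr@label, estimate = cr@estimate, se = cr@se,
        df = cr@df, stat = cr@statistic, p = cr@p)
    }
  }
  writeTsv(do.call(rbind, contrastRows),
           file.path(outDir, "contrasts.tsv"))
  manifest <- c(manifest, "contrasts.tsv")

  bpRows <- list()
  for (oc in names(outcomes)) {
    bp <- stage("analyze", fitBreakpointModel(tbl, outcomes[[oc]],
                                              config@breakpointKnot))
    results$breakpoints[[oc]] <- bp
    bpRows[[oc]] <- data.frame(
      outcome = oc, pre_slope = bp@preSlope, post_slope = bp@postSlope,
      slope_change = bp@slopeChange, level_change = bp@levelChange,
      p_breakpoint = bp@pBreakpoint, n = bp@n)
  }
  writeTsv(do.call(rbind, bpRows), file.path(outDir, "breakpoints.tsv"))
  manifest <- c(manifest, "breakpoints.tsv")
  note("analyze: efficiency breakpoint p = ",
       signif(results$breakpoints$efficiency@pBreakpoint, 3),
       ", strength breakpoint p = ",
       signif(results$breakpoints$strength@pBreakpoint, 3))

  if (length(hubSet)) {
    regional <- merge(nodalTable[, c("subject_id", "node", "strength",
                                     "hub_flag")],
                      retained[, c("subject_id", "group", "age", "site",
                                   "gene")],
                      by = "subject_id")
    results$hubInteraction <- stage("analyze",
                                    hubGapInteraction(regional))
    note("analyze: hub x group interaction p = ",
         signif(results$hubInteraction@p, 3))
  } else {
    note("analyze: empty hub set; hub interaction skipped")
  }

  assocRows <- list()
  assocSpecs <- list(
    c(x = "connection_strength_total", y = "brain_volume_pct"),
    c(x = "global_efficiency_normalized", y = "brain_volume_pct"))
  for (test in intersect(names(config@cohort@cognitionCoupling),
                         names(tbl))) {
    assocSpecs[[length(assocSpecs) + 1L]] <-
      c(x = "connection_strength_total", y = test)
  }
  for (spc in assocSpecs) {
    ar <- stage("analyze", associationByGroup(tbl, spc[["x"]],
                                              spc[["y"]]))
    key <- paste(spc[["x"]], "vs", spc[["y"]])
    results$associations[[key]] <- ar
    assocRows[[key]] <- data.frame(
      x = spc[["x"]], y = spc[["y"]],
      r_carrier = ar@r[["carrier"]], p_carrier = ar@rP[["carrier"]],
      r_ftd = ar@r[["ftd"]], p_ftd = ar@rP[["ftd"]],
      interaction_estimate = ar@interactionEstimate,
      interaction_p = ar@interactionP)
  }
  writeTsv(do.call(rbind, assocRows),
           file.path(outDir, "associations.tsv"))
  manifest <- c(manifest, "associations.tsv")

  counts <- c(generated = nrow(subjects), excluded = nrow(ex$excluded),
              retained = nrow(retained))
  stopifnot(counts[["generated"]] ==
              counts[["excluded"]] + counts[["retained"]])
  writeLines(logLines, file.path(outDir, "run.log"))
  manifest <- c(manifest, "run.log")

  new("RunReport", counts = as.integer(counts) |>
        stats::setNames(names(counts)),
      manifest = manifest, outputDir = outDir,
      seed = config@cohort@seed, band = band,
      hubSet = as.integer(hubSet), results = results, metrics = metrics,
      multipleComparisonCorrection = "none")
}
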