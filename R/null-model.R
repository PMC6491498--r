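# Degree-preserving null ensembles and hub identification.

#' Create a null-ensemble specification
#'
#' @param nNulls number of null graphs (study default 500; desk-scale
#'   runs typically use 50).
#' @param swapsPerEdge degree-preserving double-edge swaps attempted per
#'   edge of the input graph.
#' @param seed integer seed for the ensemble.
#' @return a [NullEnsembleSpec].
#' @examples
#' nullEnsembleSpec(nNulls = 50, seed = 9)
#' @export
nullEnsembleSpec <- function(nNulls = 500L, swapsPerEdge = 10L, seed = 1L) {
  new("NullEnsembleSpec", nNulls = as.integer(nNulls),
      swapsPerEdge = as.integer(swapsPerEdge), seed = as.integer(seed))
}

#' Generate a degree-preserving null ensemble
#'
#' Each null graph keeps the input's binary degree sequence (topology
#' randomized by repeated degree-preserving double-edge swaps) and its
#' exact multiset of edge weights (randomly permuted onto the rewired
#' edges). Rewiring batches that disconnect the graph are rejected and
#' rewired further until connectivity is restored, so every null is
#' connected; a complete input graph admits no swap and only its weights
#' are permuted.
#'
#' @param graph a connected [BrainGraph].
#' @param spec a [NullEnsembleSpec].
#' @return list of [BrainGraph] nulls.
#' @examples
#' v <- matrix(runif(36), 6, 6); v <- (v + t(v)) / 2; diag(v) <- 1
#' g <- buildGraph(v, targetDensity = 0.6, subjectId = "demo")
#' nulls <- generateNullEnsemble(g, nullEnsembleSpec(nNulls = 3, seed = 1))
#' @export
generateNullEnsemble <- function(graph, spec = nullEnsembleSpec()) {
  stopifnot(is(graph, "BrainGraph"), is(spec, "NullEnsembleSpec"))
  validObject(spec)
  w <- graph@weights
  n <- nrow(w)
  g0 <- asIgraph(w)
  m <- igraph::ecount(g0)
  edgeWeights <- igraph::E(g0)$weight
  complete <- m == n * (n - 1) / 2
  deg0 <- igraph::degree(g0)
  withSeed(spec@seed, {
    lapply(seq_len(spec@nNulls), function(b) {
      gb <- g0
      if (!complete) {
        gb <- igraph::rewire(
          g0, igraph::keeping_degseq(niter = spec@swapsPerEdge * m))
        tries <- 0L
        while (!igraph::is_connected(gb) && tries < 100L) {
          gb <- igraph::rewire(gb, igraph::keeping_degseq(niter = m))
          tries <- tries + 1L
        }
        if (!igraph::is_connected(gb)) {
          # last resort: draw a fresh connected realization of the
          # degree sequence
          gb <- igraph::sample_degseq(deg0, method = "vl")
        }
      }
      el <- igraph::as_edgelist(gb, names = FALSE)
      wb <- matrix(0, n, n)
      perm <- sample(edgeWeights)
      wb[el] <- perm
      wb <- wb + t(wb)
      new("BrainGraph", subjectId = paste0(graph@subjectId, "_null", b),
          weights = wb, edgeDensity = graph@edgeDensity,
          negativePolicy = graph@negativePolicy,
          targetDensity = graph@targetDensity)
    })
  })
}

#' Identify hub regions from reference strengths
#'
#' A region is flagged as a hub iff its reference connection strength
#' exceeds the across-region mean by more than `kSd` sample standard
#' deviations. In the study design the reference strengths are the
#' per-region mean nodal strengths over the gene-negative group, so the
#' hub set depends only on that group. A zero-variance strength profile
#' yields an empty hub set (not an error).
#'
#' @param referenceStrengths numeric vector of per-region reference
#'   strengths (>= 2 regions).
#' @param kSd standard-deviation multiplier (study default 2).
#' @return integer vector of hub region indices.
#' @examples
#' identifyHubs(c(1, 1, 1, 5))
#' @export
identifyHubs <- function(referenceStrengths, kSd = 2) {
  x <- as.numeric(referenceStrengths)
  if (length(x) < 2L) stop("need at least 2 regions to identify hubs")
  if (anyNA(x)) stop("reference strengths contain NA")
  s <- stats::sd(x)
  if (s == 0) return(integer(0))
  which(x > mean(x) + kSd * s)
}
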