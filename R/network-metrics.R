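# Weighted brain graphs and their strength / path-length metrics.
# Distances use the standard reciprocal transform d = 1/w for
# correlation-weighted connectomes.

asIgraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Build a thresholded weighted graph from a connectivity matrix
#'
#' Negative correlations are handled per policy (`"zero"`: set to zero,
#' the default; `"absolute"`: absolute value). A maximum-weight spanning
#' tree is retained as a backbone guaranteeing connectedness, then the
#' strongest remaining edges are added until the target edge density is
#' reached.
#'
#' @param conn a [ConnectivityMatrix] (or plain symmetric matrix with
#'   unit diagonal).
#' @param negativePolicy `"zero"` or `"absolute"`.
#' @param targetDensity proportion of possible edges to retain, in
#'   (0, 1].
#' @param subjectId identifier override when `conn` is a plain matrix.
#' @return a connected [BrainGraph].
#' @examples
#' v <- matrix(0.5, 4, 4); diag(v) <- 1
#' g <- buildGraph(new("ConnectivityMatrix", subjectId = "s",
#'                     values = v), targetDensity = 1)
#' edgeDensity(g)
#' @export
buildGraph <- function(conn, negativePolicy = c("zero", "absolute"),
                       targetDensity = 0.1, subjectId = NULL) {
  negativePolicy <- match.arg(negativePolicy)
  if (is(conn, "ConnectivityMatrix")) {
    w <- conn@values
    sid <- if (is.null(subjectId)) conn@subjectId else subjectId
  } else {
    w <- as.matrix(conn)
    sid <- if (is.null(subjectId)) "graph" else subjectId
  }
  if (!(targetDensity > 0 && targetDensity <= 1))
    stop("target_density must lie in (0, 1]")
  n <- nrow(w)
  diag(w) <- 0
  w <- switch(negativePolicy, zero = pmax(w, 0), absolute = abs(w))
  nPos <- sum(w[upper.tri(w)] > 0)
  if (nPos < n - 1 || !adjacencyConnected(w))
    stop("cannot connect the graph: fewer than n-1 usable positive ",
         "edges under negative_policy='", negativePolicy, "'")
  g <- asIgraph(w)
  # maximum-weight spanning tree: minimize (max w - w)
  wts <- igraph::E(g)$weight
  tree <- igraph::mst(g, weights = max(wts) - wts)
  treeEdges <- igraph::as_edgelist(tree, names = FALSE)

  mTarget <- max(round(targetDensity * n * (n - 1) / 2), n - 1)
  keep <- matrix(FALSE, n, n)
  keep[treeEdges] <- TRUE
  keep <- keep | t(keep)
  mHave <- n - 1
  if (mHave < mTarget) {
    ut <- which(upper.tri(w) & w > 0 & !keep)
    ut <- ut[order(w[ut], decreasing = TRUE)]
    extra <- utils::head(ut, mTarget - mHave)
    keep[extra] <- TRUE
    keep <- keep | t(keep)
    mHave <- mHave + length(extra)
  }
  w2 <- ifelse(keep, w, 0)
  new("BrainGraph", subjectId = sid, weights = w2,
      edgeDensity = mHave / (n * (n - 1) / 2),
      negativePolicy = negativePolicy, targetDensity = targetDensity)
}

graphDistances <- function(graph) {
  g <- asIgraph(graph@weights)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  if (any(!is.finite(d[upper.tri(d)])))
    stop("graph is disconnected; shortest-path metrics undefined")
  d
}

#' Nodal network metrics
#'
#' Per-node connection strength (weighted degree: sum of incident edge
#' weights), farness (mean shortest-path length to the other n-1 nodes;
#' the study's "closeness centrality", lower = better integrated) and
#' nodal efficiency (mean inverse shortest-path length). Path lengths
#' use edge length 1/weight.
#'
#' @param graph a connected [BrainGraph].
#' @return data.frame with columns `node`, `strength`, `farness`,
#'   `nodal_efficiency`.
#' @examples
#' v <- matrix(1, 3, 3); diag(v) <- 1
#' g <- buildGraph(v, targetDensity = 1, subjectId = "demo")
#' computeNodalMetrics(g)
#' @export
computeNodalMetrics <- function(graph) {
  stopifnot(is(graph, "BrainGraph"))
  d <- graphDistances(graph)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  data.frame(node = seq_len(n),
             strength = rowSums(graph@weights),
             farness = rowSums(d) / (n - 1),
             nodal_efficiency = rowSums(inv) / (n - 1))
}

#' Global network metrics with null-model normalization
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path length; total connection strength is the sum of nodal
#' strengths (twice the sum of edge weights). Efficiency and per-node
#' farness are normalized against their mean values over a
#' degree-preserving null ensemble.
#'
#' @param graph a connected [BrainGraph].
#' @param nulls list of null [BrainGraph]s from [generateNullEnsemble()];
#'   may be omitted only with `normalize = FALSE`.
#' @param normalize whether to compute null-normalized values.
#' @return a [GlobalMetrics].
#' @examples
#' v <- matrix(1, 4, 4); diag(v) <- 1
#' g <- buildGraph(v, targetDensity = 1, subjectId = "demo")
#' computeGlobalMetrics(g, normalize = FALSE)
#' @export
computeGlobalMetrics <- function(graph, nulls = list(), normalize = TRUE) {
  stopifnot(is(graph, "BrainGraph"))
  nodal <- computeNodalMetrics(graph)
  raw <- mean(nodal$nodal_efficiency)
  total <- sum(nodal$strength)
  n <- nrow(graph@weights)
  if (!normalize) {
    return(new("GlobalMetrics", subjectId = graph@subjectId,
               connectionStrengthTotal = total, globalEfficiencyRaw = raw,
               globalEfficiencyNormalized = NA_real_,
               closenessNormalized = rep(NA_real_, n), nNulls = 0L))
  }
  if (!length(nulls))
    stop("normalization requested but the null ensemble is empty; ",
         "pass nulls from generateNullEnsemble() or normalize = FALSE")
  nullEff <- numeric(length(nulls))
  nullFar <- matrix(NA_real_, length(nulls), n)
  for (b in seq_along(nulls)) {
    nb <- computeNodalMetrics(nulls[[b]])
    nullEff[b] <- mean(nb$nodal_efficiency)
    nullFar[b, ] <- nb$farness
  }
  new("GlobalMetrics", subjectId = graph@subjectId,
      connectionStrengthTotal = total, globalEfficiencyRaw = raw,
      globalEfficiencyNormalized = raw / mean(nullEff),
      closenessNormalized = nodal$farness / colMeans(nullFar),
      nNulls = length(nulls))
}
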