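## Standard connectivity and distance metrics
## ------------------------------------------
## Shortest-path machinery is delegated to igraph; weighted path lengths
## use the connectivity-weight convention l = 1/w, so heavier edges are
## shorter. Disconnected pairs carry the Inf sentinel in distance
## matrices and contribute 0 to efficiency.

.metricNames <- c("Deg", "Sw", "BC", "BCw", "Cm", "Cmw", "CBC", "CBCw")

#' Degree and strength of every node
#'
#' @param x a \linkS4class{Connectome}.
#' @return List with named numeric vectors \code{degree}
#'   (\code{Deg[i] = } number of neighbors) and \code{strength}
#'   (\code{Sw[i] = } sum of incident weights).
#' @export
degreeStrength <- function(x) {
  stopifnot(is(x, "Connectome"))
  W <- weightMatrix(x)
  deg <- rowSums(W > 0)
  sw <- rowSums(W)
  names(deg) <- names(sw) <- x@labels
  list(degree = deg, strength = sw)
}

#' Shortest-path distance matrix
#'
#' Binary distances are hop counts; weighted distances minimize the sum
#' of inverse weights \code{1/w} along the path. Disconnected pairs get
#' \code{Inf}.
#'
#' @param x a \linkS4class{Connectome}.
#' @param weighted logical.
#' @return A \linkS4class{PairMatrix} of kind \code{"dist_binary"} or
#'   \code{"dist_weighted"}.
#' @export
distanceMatrix <- function(x, weighted = FALSE) {
  stopifnot(is(x, "Connectome"))
  g <- .asGraph(weightMatrix(x))
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  D <- igraph::distances(g, weights = w)
  D <- pmin(D, t(D))  # Dijkstra can differ in the last ulp across directions
  dimnames(D) <- NULL
  .PairMatrix(if (weighted) "dist_weighted" else "dist_binary", D, x@labels)
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized betweenness with fractional credit over equally short
#' paths; the weighted form uses \code{1/w} edge lengths.
#'
#' @param x a \linkS4class{Connectome}.
#' @param weighted logical.
#' @return Named numeric vector.
#' @export
betweennessCentrality <- function(x, weighted = FALSE) {
  stopifnot(is(x, "Connectome"))
  g <- .asGraph(weightMatrix(x))
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  b <- igraph::betweenness(g, directed = FALSE, weights = w)
  names(b) <- x@labels
  b
}

#' Global efficiency
#'
#' \code{Eff = mean over ordered pairs of 1/d(i, j)} with \code{1/Inf = 0},
#' so disconnection lowers efficiency smoothly. Bounded by [0, 1] for
#' binary networks (1 for a complete graph).
#'
#' @param x a \linkS4class{Connectome} with at least 2 nodes.
#' @param weighted use weighted distances (\code{1/w} lengths).
#' @return A scalar.
#' @export
globalEfficiency <- function(x, weighted = FALSE) {
  stopifnot(is(x, "Connectome"))
  n <- nNodes(x)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  D <- pairValues(distanceMatrix(x, weighted = weighted))
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest-path distances, together with
#' the fraction of disconnected (infinite) pairs. When the network is
#' disconnected, efficiency is the better-behaved global summary; the
#' disconnected fraction is reported so that the restricted mean is never
#' read as if the network were connected.
#'
#' @param x a \linkS4class{Connectome} with at least 2 nodes.
#' @param weighted logical.
#' @return List with \code{cpl} (mean finite distance) and
#'   \code{disconnectedFraction}. Errors when no finite pair exists.
#' @export
characteristicPathLength <- function(x, weighted = FALSE) {
  n <- nNodes(x)
  if (n < 2) stop("characteristic path length needs at least 2 nodes")
  D <- pairValues(distanceMatrix(x, weighted = weighted))
  off <- D[upper.tri(D)]
  finite <- is.finite(off)
  if (!any(finite)) stop("no finite node pairs: network has no edges")
  list(cpl = mean(off[finite]),
       disconnectedFraction = mean(!finite))
}

#' Identify hub nodes
#'
#' Hubs are nodes whose degree is at least one standard deviation above
#' the mean degree (sample sd, n - 1 denominator), thresholded on the
#' whole network; an optional hemisphere filter is applied afterwards.
#' When all degrees are equal (sd = 0) every node meets the \code{>=}
#' rule.
#'
#' @param x a \linkS4class{Connectome}.
#' @param hemisphere optional \code{"L"} or \code{"R"} restriction.
#' @return Integer vector of node indices (possibly empty).
#' @export
identifyHubs <- function(x, hemisphere = NULL) {
  stopifnot(is(x, "Connectome"))
  deg <- degreeStrength(x)$degree
  thr <- mean(deg) + stats::sd(deg)
  hubs <- which(deg >= thr)
  if (!is.null(hemisphere)) {
    hubs <- hubs[x@hemisphere[hubs] == hemisphere]
  }
  unname(hubs)
}

#' Communicability assortativity: matrix reordered by degree or strength
#'
#' Reorders the communicability matrix by increasing degree (binary) or
#' strength (weighted) and summarizes the block structure: mean
#' communicability within the top-k block, within the bottom-k block, and
#' between the two. Positive assortative communicability shows as a
#' top-block mean exceeding the other two.
#'
#' @param x a \linkS4class{Connectome}.
#' @param weighted use \code{Cm^w} ordered by strength instead of
#'   \code{Cm} ordered by degree.
#' @param k block size; default 50, capped at \code{floor(n/2)}.
#' @return List with \code{matrix} (reordered \linkS4class{PairMatrix}),
#'   \code{order} (node indices by increasing metric) and
#'   \code{blockMeans} (named vector: top, bottom, cross).
#' @export
communicabilityAssortativity <- function(x, weighted = FALSE, k = 50) {
  stopifnot(is(x, "Connectome"))
  n <- nNodes(x)
  k <- min(k, floor(n / 2))
  ds <- degreeStrength(x)
  key <- if (weighted) ds$strength else ds$degree
  ord <- order(key, seq_len(n))  # ties by lowest index
  pm <- if (weighted) communicabilityWeighted(x) else communicabilityBinary(x)
  V <- pairValues(pm)[ord, ord, drop = FALSE]
  blockMean <- function(rows, cols) {
    sub <- V[rows, cols, drop = FALSE]
    if (identical(rows, cols)) {
      off <- sub[upper.tri(sub) | lower.tri(sub)]
      if (length(off) == 0) 0 else mean(off)
    } else {
      mean(sub)
    }
  }
  bottom <- seq_len(k)
  top <- seq.int(n - k + 1, n)
  bm <- if (k >= 1) {
    c(top = blockMean(top, top), bottom = blockMean(bottom, bottom),
      cross = blockMean(top, bottom))
  } else {
    c(top = 0, bottom = 0, cross = 0)
  }
  list(matrix = .PairMatrix(pm@kind, V, x@labels[ord]),
       order = ord, blockMeans = bm)
}

#' Density of the subgraph induced by the top-k nodes of a metric
#'
#' @param x a \linkS4class{Connectome}.
#' @param metric numeric vector, one value per node.
#' @param k number of top nodes, \code{2 <= k <= n}; ties are broken by
#'   lowest node index.
#' @return Edges present among the k nodes divided by \code{k(k-1)/2}.
#' @export
topNodeDensity <- function(x, metric, k) {
  stopifnot(is(x, "Connectome"))
  n <- nNodes(x)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  if (length(metric) != n) stop("metric length != n_nodes")
  top <- order(-metric, seq_len(n))[seq_len(k)]
  sub <- weightMatrix(x)[top, top]
  sum(sub[upper.tri(sub)] > 0) / (k * (k - 1) / 2)
}

#' Compute one node-level metric by name
#'
#' Dispatcher used by targeted attacks and the pipeline reports. Metric
#' names: \code{Deg}, \code{Sw} (strength), \code{BC}, \code{BCw}
#' (betweenness), \code{Cm}, \code{Cmw} (node-level communicability,
#' weighted form strength-normalized), \code{CBC}, \code{CBCw}
#' (communicability centrality).
#'
#' @param x a \linkS4class{Connectome}.
#' @param metric one of the eight names above.
#' @return Named numeric vector, one value per node.
#' @export
nodeMetric <- function(x, metric = .metricNames) {
  metric <- match.arg(metric)
  switch(metric,
         Deg = degreeStrength(x)$degree,
         Sw = degreeStrength(x)$strength,
         BC = betweennessCentrality(x, weighted = FALSE),
         BCw = betweennessCentrality(x, weighted = TRUE),
         Cm = nodeCommunicability(communicabilityBinary(x)),
         Cmw = nodeCommunicability(communicabilityWeighted(x)),
         CBC = communicabilityCentrality(x, weighted = FALSE),
         CBCw = communicabilityCentrality(x, weighted = TRUE))
}

#' Table of node-level metrics
#'
#' @param x a \linkS4class{Connectome}.
#' @param metrics subset of the eight metric names; default all.
#' @return data.frame with index, label, hemisphere and one column per
#'   metric.
#' @export
nodeMetricTable <- function(x, metrics = .metricNames) {
  metrics <- match.arg(metrics, .metricNames, several.ok = TRUE)
  d <- data.frame(index = seq_len(nNodes(x)), label = x@labels,
                  hemisphere = x@hemisphere, stringsAsFactors = FALSE)
  for (m in metrics) d[[m]] <- unname(nodeMetric(x, m))
  d
}

#' Hemispheric means of a node metric
#'
#' @param x a \linkS4class{Connectome}.
#' @param values numeric vector, one value per node.
#' @return Named numeric vector with the mean over L and over R nodes.
#' @export
hemisphericMeans <- function(x, values) {
  stopifnot(length(values) == nNodes(x))
  c(L = mean(values[x@hemisphere == "L"]),
    R = mean(values[x@hemisphere == "R"]))
}
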