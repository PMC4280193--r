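## Group statistics for lesion experiments
## ---------------------------------------
## Efficiency decay curves are compared with a label-shuffling permutation
## test; per-node metric changes with classical paired t-tests and
## Benjamini-Hochberg FDR correction; and local changes are related to
## the distance from the lesion focus with Pearson (weighted distance) or
## Spearman (binary/ordinal distance) correlations.

## paired t-test on two matched vectors; returns t, p and a zero-variance
## flag. All-zero differences -> t = 0, p = 1 (no change); identical
## non-zero differences -> |t| = Inf, p = 0, flagged.
.pairedT <- function(a, b) {
  d <- a - b
  ns <- length(d)
  if (ns < 2) stop("paired t-test needs at least 2 subjects")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, zeroVariance = TRUE))
    return(list(t = sign(m) * Inf, p = 0, zeroVariance = TRUE))
  }
  t <- m / (s / sqrt(ns))
  list(t = t, p = 2 * stats::pt(-abs(t), df = ns - 1), zeroVariance = FALSE)
}

#' Permutation test comparing two sets of efficiency decay curves
#'
#' The statistic is the sum over lesion steps of the difference in group
#' mean efficiency, \code{T = sum_s (mean_A(s) - mean_B(s))}. Group
#' labels are shuffled across the pooled curves \code{nPerm} times and
#' the two-sided p-value is \code{(#\{|T_perm| >= |T_obs|\} + 1) /
#' (nPerm + 1)}, which includes the observed labeling in the null set so
#' p is never 0.
#'
#' @param curvesA,curvesB numeric matrices, one curve per row, equal
#'   column counts.
#' @param nPerm number of permutations (default 5000).
#' @param seed optional seed for the permutation draws.
#' @return List with \code{statistic} (observed T), \code{p} and
#'   \code{nPerm}.
#' @export
permutationTestCurves <- function(curvesA, curvesB, nPerm = 5000L,
                                  seed = NULL) {
  curvesA <- rbind(curvesA)
  curvesB <- rbind(curvesB)
  if (ncol(curvesA) != ncol(curvesB)) stop("curve length mismatch")
  if (nrow(curvesA) == 0 || nrow(curvesB) == 0) stop("both sets must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  pooled <- rbind(curvesA, curvesB)
  na <- nrow(curvesA)
  n <- nrow(pooled)
  stat <- function(idxA) {
    sum(colMeans(pooled[idxA, , drop = FALSE]) -
          colMeans(pooled[-idxA, , drop = FALSE]))
  }
  tObs <- stat(seq_len(na))
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    idx <- sample(n, na)
    if (abs(stat(idx)) >= abs(tObs)) exceed <- exceed + 1L
  }
  list(statistic = tObs, p = (exceed + 1) / (nPerm + 1), nPerm = nPerm)
}

#' Per-node paired t-tests between two metric matrices
#'
#' @param baseline,lesioned numeric subjects-by-nodes matrices of one
#'   metric, matching shapes, at least two subjects.
#' @return data.frame with one row per node: \code{meanChange}
#'   (baseline − lesioned), \code{t}, \code{p}, \code{zeroVariance}.
#'   Nodes whose subject-wise differences are all exactly zero get
#'   \code{t = 0, p = 1}; identical non-zero differences get the flagged
#'   \code{p = 0} sentinel.
#' @export
pairedTTestPerNode <- function(baseline, lesioned) {
  if (!all(dim(baseline) == dim(lesioned))) stop("shape mismatch")
  if (nrow(baseline) < 2) stop("need at least 2 subjects")
  res <- lapply(seq_len(ncol(baseline)), function(j) {
    .pairedT(baseline[, j], lesioned[, j])
  })
  data.frame(node = seq_len(ncol(baseline)),
             meanChange = colMeans(baseline - lesioned),
             t = vapply(res, `[[`, numeric(1), "t"),
             p = vapply(res, `[[`, numeric(1), "p"),
             zeroVariance = vapply(res, `[[`, logical(1), "zeroVariance"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), delegating to
#' \code{\link[stats]{p.adjust}} after validating the input range.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
fdrAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-node change report with FDR correction
#'
#' Runs \code{\link{pairedTTestPerNode}}, adjusts across nodes with
#' Benjamini-Hochberg (the FDR family is one metric at one lesion step),
#' and marks significance at \code{pAdj < alpha}.
#'
#' @param baseline,lesioned subjects-by-nodes metric matrices.
#' @param alpha significance level after correction (default 0.05).
#' @param labels optional node labels.
#' @return data.frame with node, label, meanChange, t, p, pAdj,
#'   significant, zeroVariance.
#' @export
changeReport <- function(baseline, lesioned, alpha = 0.05, labels = NULL) {
  rep <- pairedTTestPerNode(baseline, lesioned)
  rep$pAdj <- fdrAdjust(rep$p)
  rep$significant <- rep$pAdj < alpha
  rep$label <- if (is.null(labels)) as.character(rep$node) else labels
  rep[, c("node", "label", "meanChange", "t", "p", "pAdj", "significant",
          "zeroVariance")]
}

#' Sensitivity summary over ordered per-step change reports
#'
#' @param reports list of \code{\link{changeReport}} data.frames ordered
#'   by lesion step.
#' @param excludeNodes optional node indices (e.g. lesioned nodes) not
#'   counted as changes.
#' @return List with \code{nSignificant} (count per step),
#'   \code{totalSignificant} and \code{earliestStep} (first step with a
#'   significant node; \code{Inf} when none).
#' @export
sensitivitySummary <- function(reports, excludeNodes = NULL) {
  if (length(reports) == 0) stop("no reports")
  counts <- vapply(reports, function(r) {
    sig <- r$significant
    if (!is.null(excludeNodes)) sig <- sig[!r$node %in% excludeNodes]
    sum(sig)
  }, numeric(1))
  earliest <- if (any(counts > 0)) min(which(counts > 0)) else Inf
  list(nSignificant = unname(counts), totalSignificant = sum(counts),
       earliestStep = earliest)
}

#' Distance of every node from a lesion focus
#'
#' The minimum over the lesion nodes of the hop distance, weighted
#' (\code{1/w}) shortest-path distance, or Euclidean distance between
#' node coordinates. Lesion nodes themselves get 0; downstream
#' correlation analyses exclude them.
#'
#' @param x a \linkS4class{Connectome}.
#' @param lesionNodes node indices or labels of the lesion focus.
#' @param kind \code{"binary"}, \code{"weighted"} or \code{"euclidean"}.
#' @return Numeric vector of distances (Inf for unreachable nodes).
#' @export
distanceFromLesion <- function(x, lesionNodes,
                               kind = c("binary", "weighted", "euclidean")) {
  stopifnot(is(x, "Connectome"))
  kind <- match.arg(kind)
  sites <- .resolveNodes(lesionNodes, x@labels)
  if (length(sites) == 0) stop("lesionNodes must be non-empty")
  if (kind == "euclidean") {
    xyz <- nodeCoords(x)
    if (is.null(xyz)) stop("euclidean distance requires node coordinates")
    d <- apply(vapply(sites, function(s) {
      sqrt(colSums((t(xyz) - xyz[s, ])^2))
    }, numeric(nNodes(x))), 1, min)
  } else {
    D <- pairValues(distanceMatrix(x, weighted = (kind == "weighted")))
    d <- apply(D[, sites, drop = FALSE], 1, min)
  }
  unname(d)
}

#' Correlate per-node changes with distance from the lesion
#'
#' @param changes,distances numeric vectors, one value per node.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param excludeNodes node indices dropped before correlating (lesion
#'   sites, by convention). Non-finite distances are always dropped.
#' @return The correlation coefficient, or \code{NA} (documented
#'   degenerate-input sentinel) when fewer than 3 usable pairs remain or
#'   either vector is constant.
#' @export
correlateChangeDistance <- function(changes, distances,
                                    method = c("pearson", "spearman"),
                                    excludeNodes = NULL) {
  method <- match.arg(method)
  if (length(changes) != length(distances)) stop("length mismatch")
  keep <- is.finite(distances) & is.finite(changes)
  if (!is.null(excludeNodes)) keep[excludeNodes] <- FALSE
  x <- changes[keep]
  y <- distances[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Change-versus-distance correlation table
#'
#' Assembles, for each metric and distance kind, the per-subject
#' ("individual") correlation coefficients summarized as mean and sd,
#' and the "average-curve" coefficient correlating the across-subject
#' mean change with the across-subject mean distance. By convention the
#' weighted and Euclidean distances use Pearson and the (ordinal) binary
#' hop distance uses Spearman; both conventions can be overridden via
#' \code{methods}.
#'
#' @param changes named list, one subjects-by-nodes change matrix per
#'   metric.
#' @param distances named list, one subjects-by-nodes distance matrix per
#'   distance kind (\code{DistW}, \code{DistB}, \code{DistE}).
#' @param lesionNodes node indices excluded from all correlations.
#' @param methods named character vector mapping distance kind to
#'   correlation method.
#' @return data.frame with metric, distKind, method, individualMean,
#'   individualSd, average.
#' @export
distanceCorrelationTable <- function(changes, distances, lesionNodes = NULL,
                                     methods = c(DistW = "pearson",
                                                 DistB = "spearman",
                                                 DistE = "pearson")) {
  rows <- list()
  for (m in names(changes)) {
    ch <- changes[[m]]
    for (dk in names(distances)) {
      dm <- distances[[dk]]
      method <- if (dk %in% names(methods)) methods[[dk]] else "pearson"
      indiv <- vapply(seq_len(nrow(ch)), function(s) {
        correlateChangeDistance(ch[s, ], dm[s, ], method = method,
                                excludeNodes = lesionNodes)
      }, numeric(1))
      avg <- correlateChangeDistance(colMeans(ch), colMeans(dm),
                                     method = method,
                                     excludeNodes = lesionNodes)
      rows[[paste(m, dk)]] <- data.frame(
        metric = m, distKind = dk, method = method,
        individualMean = mean(indiv, na.rm = TRUE),
        individualSd = stats::sd(indiv[!is.na(indiv)]),
        average = avg, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Ranked table of where significant changes concentrate
#'
#' Across repetitions (or lesion specifications), counts for every node
#' the fraction of reports in which it was among the most significant
#' changes — the top-\code{k} significant nodes by adjusted p-value —
#' excluding the damaged nodes.
#'
#' @param reports list of \code{\link{changeReport}} data.frames.
#' @param damagedNodes node indices excluded from the ranking.
#' @param k how many top nodes count per report (default 10).
#' @return data.frame (node, label, fraction), sorted by decreasing
#'   fraction; empty when no report has significant nodes.
#' @export
reportChangeLocations <- function(reports, damagedNodes = NULL, k = 10L) {
  if (length(reports) == 0) stop("no reports")
  counts <- integer(0)
  labels <- character(0)
  for (r in reports) {
    cand <- r[r$significant & !(r$node %in% damagedNodes), , drop = FALSE]
    if (nrow(cand) == 0) next
    cand <- cand[order(cand$pAdj, cand$node), , drop = FALSE]
    top <- utils::head(cand, k)
    for (i in seq_len(nrow(top))) {
      key <- as.character(top$node[i])
      counts[key] <- if (key %in% names(counts)) counts[key] + 1L else 1L
      labels[key] <- top$label[i]
    }
  }
  if (length(counts) == 0) {
    return(data.frame(node = integer(0), label = character(0),
                      fraction = numeric(0)))
  }
  out <- data.frame(node = as.integer(names(counts)),
                    label = unname(labels[names(counts)]),
                    fraction = unname(counts) / length(reports),
                    stringsAsFactors = FALSE)
  out[order(-out$fraction, out$node), , drop = FALSE]
}
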