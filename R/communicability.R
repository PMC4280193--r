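## Communicability metrics
## -----------------------
## Communicability counts all walks between two nodes with factorial
## down-weighting: Cm = exp(A) = sum_k A^k / k!. The weighted form first
## normalizes by node strength, Cm^w = exp(S^{-1/2} W S^{-1/2}), which
## damps the otherwise dominant contribution of high-strength nodes.
## All matrices here are symmetric, so the exponential is computed by
## spectral decomposition, which keeps it exactly symmetric and handles
## negative eigenvalues without series truncation error.

## matrix exponential of a symmetric matrix via eigendecomposition
.symExpm <- function(M) {
  if (nrow(M) == 0) return(M)
  e <- eigen(M, symmetric = TRUE)
  E <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (E + t(E)) / 2
}

## zero out entries between different connected components (their true
## communicability is exactly 0; the eigensolver leaves ~1e-16 residue)
## and clamp tiny negative off-diagonal residues to 0
.cleanCm <- function(E, W) {
  comp <- .components(W)
  cross <- outer(comp, comp, "!=")
  E[cross] <- 0
  E[E < 0] <- 0
  E
}

## strength-normalized weighted matrix D W D, D = diag(1/sqrt(s_i));
## isolated nodes (s_i = 0) keep 1/sqrt(s_i) := 0 so they stay isolated
.normalizedWeights <- function(W) {
  s <- rowSums(W)
  d <- ifelse(s > 0, 1 / sqrt(s), 0)
  W * outer(d, d)
}

#' Binary communicability matrix
#'
#' \code{Cm = exp(A)}: entry \code{(i, j)} sums the number of walks of
#' every length between i and j, each divided by the factorial of its
#' length. The diagonal is at least 1 (the empty walk) and off-diagonal
#' entries between different connected components are exactly 0.
#'
#' @param x a \linkS4class{Connectome}.
#' @return A \linkS4class{PairMatrix} of kind \code{"cm_binary"}.
#' @examples
#' W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
#' pairValues(communicabilityBinary(Connectome(W)))[1, 2]  # sinh(1)
#' @export
communicabilityBinary <- function(x) {
  stopifnot(is(x, "Connectome"))
  A <- adjacency(x)
  E <- .cleanCm(.symExpm(A), A)
  .PairMatrix("cm_binary", E, x@labels)
}

#' Weighted communicability matrix
#'
#' With \code{normalize = TRUE} (the default, and the form used throughout
#' the lesion analyses), \code{Cm^w = exp(S^{-1/2} W S^{-1/2})} where
#' \code{S = diag(s_i)} holds node strengths; the normalization makes the
#' result invariant to a global rescaling of \code{W} and regulates the
#' influence of high-strength nodes. With \code{normalize = FALSE} the
#' plain \code{exp(W)} is returned. Isolated nodes are left isolated
#' (their strength normalization is defined as 0).
#'
#' @param x a \linkS4class{Connectome}.
#' @param normalize apply the strength normalization (default TRUE).
#' @return A \linkS4class{PairMatrix} of kind \code{"cm_weighted"}.
#' @export
communicabilityWeighted <- function(x, normalize = TRUE) {
  stopifnot(is(x, "Connectome"))
  W <- weightMatrix(x)
  M <- if (normalize) .normalizedWeights(W) else W
  E <- .cleanCm(.symExpm(M), W)
  .PairMatrix("cm_weighted", E, x@labels)
}

#' Node-level communicability
#'
#' Aggregates a communicability matrix to one value per node as the row
#' sum excluding the diagonal — the communicability analogue of strength.
#'
#' @param pm a \linkS4class{PairMatrix} of kind \code{"cm_binary"} or
#'   \code{"cm_weighted"}.
#' @return Named numeric vector, one entry per node.
#' @export
nodeCommunicability <- function(pm) {
  stopifnot(is(pm, "PairMatrix"))
  if (!startsWith(pm@kind, "cm")) {
    stop("nodeCommunicability requires a communicability PairMatrix, got kind '",
         pm@kind, "'")
  }
  v <- rowSums(pm@values) - diag(pm@values)
  names(v) <- pm@labels
  v
}

#' Communicability centrality (CBC)
#'
#' Measures how much the communicability among all other node pairs drops
#' when one node is removed. For node r, the network is lesioned by
#' zeroing r's row and column (walk-equivalent, for retained pairs, to
#' deleting the node) and
#' \deqn{CBC(r) = \frac{1}{K} \sum_{i \ne j,\; i,j \ne r}
#'   \frac{Cm_{ij} - Cm^{(r)}_{ij}}{Cm_{ij}},}
#' where the sum runs over ordered pairs with \code{Cm[i, j] > 0} and K is
#' the number of terms. Because lesioning can only remove walks, each term
#' lies in [0, 1] and so does CBC; a value of 1 means the node's removal
#' disconnects every remaining communicating pair (e.g. the center of a
#' star), 0 means it carries no walks between others (e.g. an isolated
#' node).
#'
#' For the weighted form the intact strength normalization is kept when
#' exponentiating the lesioned network (\code{renormalize = FALSE}, the
#' default), which preserves the [0, 1] bound; recomputing strengths on
#' the lesioned network (\code{renormalize = TRUE}) is available for
#' sensitivity checks but can push values outside [0, 1], because lowered
#' strengths inflate the remaining normalized weights.
#'
#' \code{relative = FALSE} gives the absolute-reduction variant
#' \code{mean(Cm - Cm^(r))} over the same pairs (not bounded by 1).
#'
#' @param x a \linkS4class{Connectome} with at least 3 nodes.
#' @param weighted use the strength-normalized weighted communicability.
#' @param renormalize recompute strengths on each lesioned network
#'   (weighted form only; see above).
#' @param relative divide each reduction by the intact communicability
#'   (default TRUE).
#' @return Named numeric vector of centralities, one per node.
#' @export
communicabilityCentrality <- function(x, weighted = FALSE,
                                      renormalize = FALSE, relative = TRUE) {
  stopifnot(is(x, "Connectome"))
  n <- nNodes(x)
  if (n < 3) stop("communicability centrality needs at least 3 nodes")
  W <- if (weighted) weightMatrix(x) else adjacency(x)
  M0 <- if (weighted) .normalizedWeights(W) else W
  Cm <- .cleanCm(.symExpm(M0), W)
  s <- rowSums(W)
  d0 <- ifelse(s > 0, 1 / sqrt(s), 0)
  deg <- rowSums(W > 0)
  out <- numeric(n)
  for (r in seq_len(n)) {
    if (deg[r] == 0) { out[r] <- 0; next }
    Wr <- W
    Wr[r, ] <- 0
    Wr[, r] <- 0
    Mr <- if (!weighted) {
      Wr
    } else if (renormalize) {
      .normalizedWeights(Wr)
    } else {
      Wr * outer(d0, d0)
    }
    Cmr <- .cleanCm(.symExpm(Mr), Wr)
    mask <- Cm > 0
    diag(mask) <- FALSE
    mask[r, ] <- FALSE
    mask[, r] <- FALSE
    K <- sum(mask)
    if (K == 0) { out[r] <- 0; next }
    if (relative) {
      ratio <- (Cm[mask] - Cmr[mask]) / Cm[mask]
      if (!renormalize) ratio <- pmin(pmax(ratio, 0), 1)  # numerical guard
      out[r] <- sum(ratio) / K
    } else {
      out[r] <- sum(Cm[mask] - Cmr[mask]) / K
    }
  }
  names(out) <- x@labels
  out
}
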