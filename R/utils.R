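#' Derive a reproducible sub-seed from a root seed and a stream label
#'
#' All stochastic components of the package draw from streams derived with
#' this function, so that a single root seed determines every random draw
#' while distinct stages (subjects, repetitions, scan noise, target draws)
#' use effectively independent streams. The derivation hashes the label
#' into a 31-bit integer and mixes it with the root seed.
#'
#' @param seed integer root seed.
#' @param ... character or numeric labels identifying the stream
#'   (e.g. \code{"subject"}, \code{3}, \code{"rep"}, \code{7}).
#' @return A single integer in \code{[0, 2^31 - 2]} suitable for
#'   \code{\link{set.seed}}.
#' @export
deriveSeed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## round half away from zero (base round() rounds half to even)
.roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

## igraph view of a weight matrix; weights kept as attribute
.asGraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

## connected component membership from a weight matrix
.components <- function(W) {
  igraph::components(.asGraph(W))$membership
}

## upper-triangle edge list of a weight matrix: data.frame(i, j, w)
.edgeList <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             w = W[idx, drop = FALSE])
}

## resolve node labels or indices to integer indices
.resolveNodes <- function(nodes, labels) {
  if (is.character(nodes)) {
    idx <- match(nodes, labels)
    if (anyNA(idx)) {
      stop("unknown node label(s): ",
           paste(nodes[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1L) || any(idx > length(labels))) {
      stop("node index out of range")
    }
    idx
  }
}

## deterministic max: ties broken by lowest index
.whichMaxFirst <- function(x) which.max(x)

## write a data.frame as TSV (the package's tabular output dialect)
.writeTSV <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
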