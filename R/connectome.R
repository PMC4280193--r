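#' Construct a Connectome
#'
#' @param W symmetric non-negative numeric matrix with zero diagonal.
#'   Small asymmetries (relative magnitude below \code{symTol}) are
#'   symmetrized by averaging; larger ones are an error.
#' @param labels character region names (default \code{"node1"} ...).
#' @param hemisphere per-node tags in \code{c("L", "R", "other")}; default
#'   assigns the first half \code{"L"} and the rest \code{"R"}.
#' @param coords optional \code{n x 3} coordinate matrix (mm).
#' @param nodeSize optional positive per-node sizes (voxels).
#' @param symTol relative tolerance for symmetrization.
#' @return A validated \linkS4class{Connectome}.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 2
#' con <- Connectome(W)
#' nNodes(con)
#' @export
Connectome <- function(W, labels = NULL, hemisphere = NULL, coords = NULL,
                       nodeSize = NULL, symTol = 1e-8) {
  W <- as.matrix(W)
  if (!is.numeric(W)) stop("W must be numeric")
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (any(!is.finite(W))) stop("W contains non-finite entries")
  if (any(W < 0)) stop("W contains negative weights")
  asym <- max(abs(W - t(W)))
  scale <- max(abs(W), 1)
  if (asym > symTol * scale) {
    stop(sprintf("W is asymmetric beyond tolerance (max |W - t(W)| = %g)", asym))
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- NULL
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  if (is.null(hemisphere)) {
    hemisphere <- rep("other", n)
    if (n >= 2) hemisphere <- ifelse(seq_len(n) <= n / 2, "L", "R")
  }
  coords <- if (is.null(coords)) {
    matrix(numeric(0), 0, 3)
  } else {
    m <- as.matrix(coords); dimnames(m) <- NULL; m
  }
  nodeSize <- if (is.null(nodeSize)) numeric(0) else as.numeric(nodeSize)
  new("Connectome", W = W, labels = as.character(labels),
      hemisphere = as.character(hemisphere), coords = coords,
      nodeSize = nodeSize)
}

#' Construct a Cohort
#'
#' @param subjectIds unique character subject identifiers.
#' @param scanA,scanB lists of \linkS4class{Connectome}, one per subject,
#'   all sharing node order.
#' @param atlasName free-text parcellation name.
#' @return A validated \linkS4class{Cohort}.
#' @export
Cohort <- function(subjectIds, scanA, scanB, atlasName = "unspecified") {
  new("Cohort", subjectIds = as.character(subjectIds),
      scanA = unname(scanA), scanB = unname(scanB),
      atlasName = atlasName)
}

## internal PairMatrix constructor (values assumed already clean)
.PairMatrix <- function(kind, values, labels) {
  dimnames(values) <- NULL
  new("PairMatrix", kind = kind, values = values, labels = labels)
}

#' @describeIn nNodes node count of a connectome
#' @export
setMethod("nNodes", "Connectome", function(x) nrow(x@W))

#' @describeIn nNodes matrix dimension of a pair matrix
#' @export
setMethod("nNodes", "PairMatrix", function(x) nrow(x@values))

#' @describeIn weightMatrix weight matrix of a connectome
#' @export
setMethod("weightMatrix", "Connectome", function(x) x@W)

#' @describeIn adjacency binary adjacency of a connectome
#' @export
setMethod("adjacency", "Connectome", function(x) (x@W > 0) * 1)

#' @describeIn nodeLabels labels of a connectome
#' @export
setMethod("nodeLabels", "Connectome", function(x) x@labels)

#' @describeIn nodeLabels labels of a pair matrix
#' @export
setMethod("nodeLabels", "PairMatrix", function(x) x@labels)

#' @describeIn hemispheres hemisphere tags of a connectome
#' @export
setMethod("hemispheres", "Connectome", function(x) x@hemisphere)

#' @describeIn nodeCoords coordinates of a connectome (or NULL)
#' @export
setMethod("nodeCoords", "Connectome", function(x) {
  if (nrow(x@coords) == 0) NULL else x@coords
})

#' @describeIn nodeSizes node sizes of a connectome (or NULL)
#' @export
setMethod("nodeSizes", "Connectome", function(x) {
  if (length(x@nodeSize) == 0) NULL else x@nodeSize
})

#' @describeIn nSubjects subject count of a cohort
#' @export
setMethod("nSubjects", "Cohort", function(x) length(x@subjectIds))

#' @describeIn subjectIds ids of a cohort
#' @export
setMethod("subjectIds", "Cohort", function(x) x@subjectIds)

.pickSubject <- function(x, subject) {
  if (is.character(subject)) match(subject, x@subjectIds) else as.integer(subject)
}

#' @describeIn scanA first scans of a cohort
#' @export
setMethod("scanA", "Cohort", function(x, subject) {
  if (missing(subject)) x@scanA else x@scanA[[.pickSubject(x, subject)]]
})

#' @describeIn scanB second scans of a cohort
#' @export
setMethod("scanB", "Cohort", function(x, subject) {
  if (missing(subject)) x@scanB else x@scanB[[.pickSubject(x, subject)]]
})

#' @describeIn pairValues values of a pair matrix
#' @export
setMethod("pairValues", "PairMatrix", function(x) x@values)

#' @describeIn pairKind kind of a pair matrix
#' @export
setMethod("pairKind", "PairMatrix", function(x) x@kind)

setMethod("show", "Connectome", function(object) {
  n <- nNodes(object)
  ne <- sum(object@W[upper.tri(object@W)] > 0)
  dens <- if (n > 1) ne / (n * (n - 1) / 2) else 0
  cat(sprintf("Connectome: %d nodes, %d edges (density %.3f)\n", n, ne, dens))
  cat(sprintf("  hemispheres: L=%d R=%d other=%d\n",
              sum(object@hemisphere == "L"), sum(object@hemisphere == "R"),
              sum(object@hemisphere == "other")))
  cat(sprintf("  coords: %s; node sizes: %s\n",
              if (nrow(object@coords)) "yes" else "no",
              if (length(object@nodeSize)) "yes" else "no"))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects x 2 scans, atlas '%s'\n",
              nSubjects(object), object@atlasName))
  if (nSubjects(object) > 0) {
    cat(sprintf("  %d nodes per network\n", nNodes(object@scanA[[1]])))
  }
})

setMethod("show", "PairMatrix", function(object) {
  cat(sprintf("PairMatrix <%s>: %d x %d\n", object@kind,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "AttackTrace", function(object) {
  cat(sprintf("AttackTrace: criterion %s, method %s, %d removals [%s]\n",
              object@criterion, object@method, length(object@removalOrder),
              object@status))
})

#' Replace the weight matrix of a connectome, keeping metadata
#'
#' Convenience used throughout the lesion simulators: returns a copy of
#' \code{x} whose weights are \code{W}, revalidated.
#' @param x a \linkS4class{Connectome}.
#' @param W the new symmetric weight matrix (same dimension).
#' @return A \linkS4class{Connectome}.
#' @export
setWeights <- function(x, W) {
  dimnames(W) <- NULL
  out <- x
  out@W <- W
  validObject(out)
  out
}
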