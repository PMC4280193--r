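#' @import methods
NULL

#' Number of nodes of a network object
#' @param x a \linkS4class{Connectome} or \linkS4class{PairMatrix}.
#' @return Integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Weighted adjacency matrix accessor
#' @param x a \linkS4class{Connectome}.
#' @return The symmetric non-negative weight matrix \code{W}.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' Binary adjacency matrix accessor
#'
#' \code{A[i, j] = 1} exactly when \code{W[i, j] > 0}.
#' @param x a \linkS4class{Connectome}.
#' @return A 0/1 matrix with zero diagonal.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Node label accessor
#' @param x a \linkS4class{Connectome} or \linkS4class{PairMatrix}.
#' @return Character vector of region names.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Hemisphere tag accessor
#' @param x a \linkS4class{Connectome}.
#' @return Character vector with entries in \code{c("L", "R", "other")}.
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' Node coordinate accessor
#' @param x a \linkS4class{Connectome}.
#' @return An \code{n x 3} matrix of coordinates (mm), or \code{NULL} when
#'   the connectome carries none.
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))

#' Node size accessor
#' @param x a \linkS4class{Connectome}.
#' @return Numeric vector of node sizes (voxels), or \code{NULL}.
#' @export
setGeneric("nodeSizes", function(x) standardGeneric("nodeSizes"))

#' Number of subjects in a cohort
#' @param x a \linkS4class{Cohort}.
#' @return Integer subject count.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Subject identifier accessor
#' @param x a \linkS4class{Cohort}.
#' @return Character vector of unique subject ids.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' First-scan accessor
#' @param x a \linkS4class{Cohort}.
#' @param subject optional subject id or index; when missing, the full list.
#' @return A \linkS4class{Connectome} or list of them.
#' @export
setGeneric("scanA", function(x, subject) standardGeneric("scanA"))

#' Second-scan accessor
#' @param x a \linkS4class{Cohort}.
#' @param subject optional subject id or index; when missing, the full list.
#' @return A \linkS4class{Connectome} or list of them.
#' @export
setGeneric("scanB", function(x, subject) standardGeneric("scanB"))

#' Pair-matrix values accessor
#' @param x a \linkS4class{PairMatrix}.
#' @return The underlying symmetric numeric matrix.
#' @export
setGeneric("pairValues", function(x) standardGeneric("pairValues"))

#' Pair-matrix kind accessor
#' @param x a \linkS4class{PairMatrix}.
#' @return One of \code{"cm_binary"}, \code{"cm_weighted"},
#'   \code{"dist_binary"}, \code{"dist_weighted"}.
#' @export
setGeneric("pairKind", function(x) standardGeneric("pairKind"))
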