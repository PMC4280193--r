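#' Connectome: one subject/scan structural brain network
#'
#' A weighted, undirected, loop-free network over a fixed parcellation.
#' Nodes are gray-matter regions carrying a label, a hemisphere tag and
#' optionally 3-D coordinates (mm) and a size (voxels); edges hold
#' non-negative connectivity weights in the symmetric matrix \code{W}.
#'
#' @slot W symmetric numeric matrix of non-negative finite weights with
#'   zero diagonal.
#' @slot labels character vector of region names, length \code{nrow(W)}.
#' @slot hemisphere character vector in \code{c("L", "R", "other")}.
#' @slot coords numeric matrix, \code{n x 3} when coordinates are present,
#'   \code{0 x 3} otherwise.
#' @slot nodeSize numeric vector of positive sizes, length \code{n} when
#'   present, length 0 otherwise.
#' @seealso \code{\link{Connectome}} for the user constructor,
#'   \code{\link{loadConnectome}} for file input.
#' @export
setClass("Connectome",
  representation(W = "matrix", labels = "character",
                 hemisphere = "character", coords = "matrix",
                 nodeSize = "numeric"),
  validity = function(object) {
    W <- object@W
    n <- nrow(W)
    msg <- character(0)
    if (ncol(W) != n) msg <- c(msg, "W must be square")
    if (!is.numeric(W) || any(!is.finite(W))) {
      msg <- c(msg, "W must be finite numeric")
    } else {
      if (any(W < 0)) msg <- c(msg, "W must be non-negative")
      if (n > 0 && any(diag(W) != 0)) msg <- c(msg, "diagonal of W must be zero")
      if (!isSymmetric(unname(W), tol = 0)) msg <- c(msg, "W must be symmetric")
    }
    if (length(object@labels) != n) msg <- c(msg, "labels length != n_nodes")
    if (length(object@hemisphere) != n) {
      msg <- c(msg, "hemisphere length != n_nodes")
    } else if (n > 0 && !all(object@hemisphere %in% c("L", "R", "other"))) {
      msg <- c(msg, "hemisphere tags must be in {L, R, other}")
    }
    if (nrow(object@coords) != 0) {
      if (nrow(object@coords) != n || ncol(object@coords) != 3) {
        msg <- c(msg, "coords must be n x 3 when present")
      }
    }
    if (length(object@nodeSize) != 0) {
      if (length(object@nodeSize) != n) {
        msg <- c(msg, "nodeSize length != n_nodes")
      } else if (any(!is.finite(object@nodeSize)) || any(object@nodeSize <= 0)) {
        msg <- c(msg, "nodeSize must be positive and finite")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Cohort: a set of subjects with two scans each
#'
#' Holds one \linkS4class{Connectome} per subject per scan session. All
#' networks in a cohort share the node order (same parcellation); which
#' scan plays the baseline role is decided at analysis time
#' (\code{\link{runLongitudinalExperiment}}).
#'
#' @slot subjectIds unique character subject identifiers.
#' @slot scanA,scanB lists of \linkS4class{Connectome}, one per subject.
#' @slot atlasName free-text name of the parcellation.
#' @export
setClass("Cohort",
  representation(subjectIds = "character", scanA = "list", scanB = "list",
                 atlasName = "character"),
  validity = function(object) {
    msg <- character(0)
    ns <- length(object@subjectIds)
    if (anyDuplicated(object@subjectIds)) msg <- c(msg, "subject ids must be unique")
    if (length(object@scanA) != ns || length(object@scanB) != ns) {
      msg <- c(msg, "scanA/scanB must have one connectome per subject")
    } else if (ns > 0) {
      all_c <- c(object@scanA, object@scanB)
      if (!all(vapply(all_c, is, logical(1), "Connectome"))) {
        msg <- c(msg, "scans must be Connectome objects")
      } else {
        ref <- all_c[[1]]@labels
        same <- vapply(all_c, function(x) identical(x@labels, ref), logical(1))
        if (!all(same)) msg <- c(msg, "all connectomes must share n_nodes and label order")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' PairMatrix: a node-by-node quantity
#'
#' Symmetric matrix of a pairwise network quantity (communicability or
#' shortest-path distance) with the node order of the source connectome.
#' Distance kinds use \code{Inf} as the disconnected-pair sentinel;
#' communicability kinds are non-negative with off-diagonal entries exactly
#' zero between different connected components.
#'
#' @slot kind one of \code{"cm_binary"}, \code{"cm_weighted"},
#'   \code{"dist_binary"}, \code{"dist_weighted"}.
#' @slot values symmetric numeric matrix.
#' @slot labels node labels of the source connectome.
#' @export
setClass("PairMatrix",
  representation(kind = "character", values = "matrix", labels = "character"),
  validity = function(object) {
    msg <- character(0)
    kinds <- c("cm_binary", "cm_weighted", "dist_binary", "dist_weighted")
    if (length(object@kind) != 1 || !object@kind %in% kinds) {
      msg <- c(msg, "kind must be one of cm_binary/cm_weighted/dist_binary/dist_weighted")
    }
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (length(object@labels) != nrow(v)) msg <- c(msg, "labels length mismatch")
    if (nrow(v) > 0) {
      if (!isSymmetric(unname(v), tol = 0)) msg <- c(msg, "values must be symmetric")
      if (any(is.na(v))) msg <- c(msg, "values must not contain NA")
      if (startsWith(object@kind, "cm") && any(v < 0)) {
        msg <- c(msg, "communicability entries must be >= 0")
      }
      if (startsWith(object@kind, "dist")) {
        if (any(v < 0)) msg <- c(msg, "distances must be >= 0")
        if (any(diag(v) != 0)) msg <- c(msg, "distance diagonal must be zero")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' LesionSpec: description of a simulated lesion experiment
#'
#' Captures everything needed to replay a lesion simulation: the lesion
#' kind, how targets are chosen, the metric criterion for targeted
#' attacks, the counts and rates, and the root RNG seed.
#'
#' @slot kind \code{"node_removal"}, \code{"node_binary"},
#'   \code{"node_weighted"} or \code{"edge_removal"}.
#' @slot targetMode \code{"single_choice"}, \code{"hubs_order"},
#'   \code{"hubs_shared"}, \code{"random_shared"},
#'   \code{"random_individual"} or \code{"fixed_list"}.
#' @slot criterion metric driving targeted attacks: one of \code{"Deg"},
#'   \code{"Sw"}, \code{"BC"}, \code{"BCw"}, \code{"Cm"}, \code{"Cmw"},
#'   \code{"CBC"}, \code{"CBCw"}.
#' @slot nTargets number of nodes attacked (\code{N}).
#' @slot rate lesion rate \code{R} in \code{(0, 1]}: fraction of a node's
#'   connections deleted (binary) or weight reduction (weighted).
#' @slot nEdges number of single-edge attacks (\code{Ne}).
#' @slot repetitions number of independent repetitions of the whole
#'   procedure with fresh random target draws.
#' @slot hemisphere optional restriction of target selection
#'   (\code{"L"}, \code{"R"} or \code{NA}).
#' @slot fixedTargets node labels for \code{targetMode = "fixed_list"}.
#' @slot seed root RNG seed, recorded in every output.
#' @export
setClass("LesionSpec",
  representation(kind = "character", targetMode = "character",
                 criterion = "character", nTargets = "integer",
                 rate = "numeric", nEdges = "integer",
                 repetitions = "integer", hemisphere = "character",
                 fixedTargets = "character", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("node_removal", "node_binary", "node_weighted",
                            "edge_removal")) {
      msg <- c(msg, "invalid kind")
    }
    if (!object@targetMode %in% c("single_choice", "hubs_order", "hubs_shared",
                                  "random_shared", "random_individual",
                                  "fixed_list")) {
      msg <- c(msg, "invalid targetMode")
    }
    if (length(object@rate) == 1 &&
        (!is.finite(object@rate) || object@rate <= 0 || object@rate > 1)) {
      msg <- c(msg, "rate must lie in (0, 1]")
    }
    if (length(object@nTargets) == 1 && object@nTargets < 0L) {
      msg <- c(msg, "nTargets must be >= 0")
    }
    if (length(object@repetitions) == 1 && object@repetitions < 1L) {
      msg <- c(msg, "repetitions must be >= 1")
    }
    if (length(msg)) msg else TRUE
  })

#' AttackTrace: record of one targeted-attack run
#'
#' Stores the removal order and the binary and weighted global efficiency
#' after every removal; index 1 of the efficiency vectors is the intact
#' network, so the vectors have length \code{N + 1} for \code{N} attacks.
#'
#' @slot criterion metric used to rank nodes.
#' @slot method \code{"single_choice"} (criterion recomputed after each
#'   removal) or \code{"hubs_order"} (ranking frozen on the intact network).
#' @slot removalOrder integer node indices (original numbering) in removal
#'   order, no duplicates.
#' @slot removedLabels labels of the removed nodes.
#' @slot effBinary,effWeighted numeric efficiency traces, intact value first.
#' @slot status \code{"complete"} or \code{"truncated"} (criterion became
#'   undefined mid-run, e.g. the network emptied).
#' @export
setClass("AttackTrace",
  representation(criterion = "character", method = "character",
                 removalOrder = "integer", removedLabels = "character",
                 effBinary = "numeric", effWeighted = "numeric",
                 status = "character"),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@removalOrder)) {
      msg <- c(msg, "removalOrder must not contain duplicates")
    }
    k <- length(object@removalOrder)
    if (length(object@removedLabels) != k) msg <- c(msg, "label/order length mismatch")
    if (length(object@effBinary) != k + 1 || length(object@effWeighted) != k + 1) {
      msg <- c(msg, "efficiency traces must have length n_removals + 1")
    }
    if (length(msg)) msg else TRUE
  })

#' CohortSpec: parameters of the synthetic two-scan cohort generator
#'
#' See \code{\link{cohortSpec}} for defaults and the meaning of each
#' parameter, and \code{\link{generateCohort}} for the generative model.
#'
#' @slot nSubjects,nNodes cohort dimensions; \code{nNodes} must be even
#'   (split half left, half right) and at least 10.
#' @slot edgeDensity target density of the group backbone.
#' @slot weightMeanlog,weightSdlog log-normal parameters of edge weights.
#' @slot hubFraction,hubMultiplier fraction of designated hub nodes per
#'   hemisphere and their connection-probability multiplier.
#' @slot interHemFraction target fraction of edges crossing hemispheres.
#' @slot scanNoiseSd standard deviation (log scale) of the mean-one
#'   multiplicative weight noise between the two scans.
#' @slot edgeJitterProb probability that an edge flips presence between
#'   scans.
#' @slot subjectEdgeProb probability a backbone edge is realized in a
#'   given subject.
#' @slot subjectSdlog log-sd of the per-subject weight deviation.
#' @slot seed root RNG seed.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", nNodes = "integer",
                 edgeDensity = "numeric", weightMeanlog = "numeric",
                 weightSdlog = "numeric", hubFraction = "numeric",
                 hubMultiplier = "numeric", interHemFraction = "numeric",
                 scanNoiseSd = "numeric", edgeJitterProb = "numeric",
                 subjectEdgeProb = "numeric", subjectSdlog = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nNodes < 10L) msg <- c(msg, "nNodes must be >= 10")
    if (object@nNodes %% 2L != 0L) msg <- c(msg, "nNodes must be even")
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    probs <- c(object@edgeDensity, object@hubFraction, object@interHemFraction,
               object@edgeJitterProb, object@subjectEdgeProb)
    if (any(probs < 0) || any(probs > 1)) {
      msg <- c(msg, "densities and probabilities must lie in [0, 1]")
    }
    if (object@scanNoiseSd < 0) msg <- c(msg, "scanNoiseSd must be >= 0")
    if (object@hubMultiplier < 1) msg <- c(msg, "hubMultiplier must be >= 1")
    if (length(msg)) msg else TRUE
  })
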