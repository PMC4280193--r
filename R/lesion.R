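#' Construct a LesionSpec
#'
#' @param kind lesion kind: \code{"node_removal"} (delete whole nodes),
#'   \code{"node_binary"} (delete a fraction R of a node's connections),
#'   \code{"node_weighted"} (scale all of a node's weights by 1 - R) or
#'   \code{"edge_removal"} (delete single edges).
#' @param targetMode how targets are chosen; see \linkS4class{LesionSpec}.
#' @param criterion ranking metric for targeted attacks.
#' @param nTargets number of target nodes N.
#' @param rate lesion rate R in (0, 1].
#' @param nEdges number of edges Ne for \code{edge_removal}.
#' @param repetitions number of repetitions with fresh target draws.
#' @param hemisphere optional \code{"L"}/\code{"R"} restriction of target
#'   selection.
#' @param fixedTargets node labels for \code{targetMode = "fixed_list"}.
#' @param seed root RNG seed.
#' @return A validated \linkS4class{LesionSpec}.
#' @export
lesionSpec <- function(kind = c("node_binary", "node_weighted",
                                "node_removal", "edge_removal"),
                       targetMode = c("hubs_shared", "random_shared",
                                      "random_individual", "single_choice",
                                      "hubs_order", "fixed_list"),
                       criterion = "Deg", nTargets = 10L, rate = 0.8,
                       nEdges = 250L, repetitions = 1L, hemisphere = NA_character_,
                       fixedTargets = character(0), seed = 1L) {
  new("LesionSpec", kind = match.arg(kind), targetMode = match.arg(targetMode),
      criterion = criterion, nTargets = as.integer(nTargets), rate = rate,
      nEdges = as.integer(nEdges), repetitions = as.integer(repetitions),
      hemisphere = hemisphere, fixedTargets = fixedTargets,
      seed = as.integer(seed))
}

#' Targeted attack: sequential node deletion by a metric criterion
#'
#' Removes \code{nAttacks} nodes one at a time, always taking the node
#' with the maximal criterion value (ties broken by lowest original
#' index), and records binary and weighted global efficiency after every
#' removal. Two selection methods:
#' \describe{
#'   \item{single_choice}{the criterion is recomputed on the lesioned
#'     network after every removal;}
#'   \item{hubs_order}{the removal order is frozen from the intact
#'     network's ranking.}
#' }
#' Node removal deletes the node's row and column, so the network shrinks
#' and efficiency is evaluated on the remaining nodes. If the criterion or
#' efficiency becomes undefined mid-run (fewer than 3 remaining nodes for
#' CBC, fewer than 2 for efficiency) the trace is truncated with status
#' \code{"truncated"}.
#'
#' @param x a \linkS4class{Connectome}.
#' @param criterion one of \code{Deg}, \code{Sw}, \code{BC}, \code{BCw},
#'   \code{Cm}, \code{Cmw}, \code{CBC}, \code{CBCw}.
#' @param method \code{"single_choice"} or \code{"hubs_order"}.
#' @param nAttacks number of nodes to remove (must be < \code{nNodes(x)}).
#' @return An \linkS4class{AttackTrace}.
#' @export
targetedAttack <- function(x, criterion = "Deg",
                           method = c("single_choice", "hubs_order"),
                           nAttacks = 1L) {
  stopifnot(is(x, "Connectome"))
  method <- match.arg(method)
  n <- nNodes(x)
  if (nAttacks >= n) stop("nAttacks must be smaller than the node count")
  needsTriple <- criterion %in% c("CBC", "CBCw")
  W <- weightMatrix(x)
  alive <- seq_len(n)      # original indices of surviving nodes
  effB <- globalEfficiency(x, weighted = FALSE)
  effW <- globalEfficiency(x, weighted = TRUE)
  order0 <- integer(0)
  if (method == "hubs_order") {
    vals <- nodeMetric(x, criterion)
    order0 <- order(-vals, seq_len(n))[seq_len(nAttacks)]
  }
  removed <- integer(0)
  status <- "complete"
  cur <- x
  for (k in seq_len(nAttacks)) {
    m <- nNodes(cur)
    if (m < 2 || (method == "single_choice" && needsTriple && m < 3)) {
      status <- "truncated"
      break
    }
    if (method == "single_choice") {
      vals <- nodeMetric(cur, criterion)
      pick_local <- .whichMaxFirst(vals)
    } else {
      pick_local <- match(order0[k], alive)
    }
    pick_orig <- alive[pick_local]
    alive <- alive[-pick_local]
    Wc <- weightMatrix(cur)[-pick_local, -pick_local, drop = FALSE]
    cur <- Connectome(Wc, labels = x@labels[alive],
                      hemisphere = x@hemisphere[alive])
    removed <- c(removed, pick_orig)
    if (nNodes(cur) < 2) {
      status <- if (k < nAttacks) "truncated" else status
      effB <- c(effB, 0)
      effW <- c(effW, 0)
      break
    }
    effB <- c(effB, globalEfficiency(cur, weighted = FALSE))
    effW <- c(effW, globalEfficiency(cur, weighted = TRUE))
  }
  new("AttackTrace", criterion = criterion, method = method,
      removalOrder = removed, removedLabels = x@labels[removed],
      effBinary = effB, effWeighted = effW, status = status)
}

#' Binary perturbation of a node: delete a fraction of its connections
#'
#' Exactly \code{round(R * Deg)} of the node's edges (half away from
#' zero, with a floor of one edge) are chosen uniformly without
#' replacement and set to zero in both triangle entries. Draws come from
#' the current RNG state; seed beforehand for reproducibility.
#'
#' @param x a \linkS4class{Connectome}.
#' @param node node index or label; must have at least one edge.
#' @param rate fraction R in (0, 1] of connections to delete.
#' @return A \linkS4class{Connectome}.
#' @export
perturbNodeBinary <- function(x, node, rate) {
  stopifnot(is(x, "Connectome"), rate > 0, rate <= 1)
  i <- .resolveNodes(node, x@labels)
  W <- weightMatrix(x)
  nbr <- which(W[i, ] > 0)
  if (length(nbr) == 0) stop("node is isolated; nothing to perturb")
  k <- max(1L, as.integer(.roundHalfUp(rate * length(nbr))))
  drop <- if (length(nbr) == 1) nbr else sample(nbr, k)
  W[i, drop] <- 0
  W[drop, i] <- 0
  setWeights(x, W)
}

#' Weighted perturbation of a node: scale all its weights down
#'
#' Every edge weight incident to the node is multiplied by \code{1 - R};
#' for R < 1 the edge set (and hence every binary metric) is unchanged,
#' for R = 1 the node becomes isolated.
#'
#' @param x a \linkS4class{Connectome}.
#' @param node node index or label.
#' @param rate weight reduction R in (0, 1].
#' @return A \linkS4class{Connectome}.
#' @export
perturbNodeWeighted <- function(x, node, rate) {
  stopifnot(is(x, "Connectome"), rate > 0, rate <= 1)
  i <- .resolveNodes(node, x@labels)
  W <- weightMatrix(x)
  W[i, ] <- W[i, ] * (1 - rate)
  W[, i] <- W[, i] * (1 - rate)
  setWeights(x, W)
}

#' Remove randomly chosen single edges
#'
#' \code{nEdges} distinct edges are drawn uniformly and removed; the
#' ordered list is returned so any intermediate network (after the first
#' k removals) can be reconstructed. Draws come from the current RNG
#' state.
#'
#' @param x a \linkS4class{Connectome}.
#' @param nEdges number of edges Ne to remove (at most the edge count).
#' @return List with \code{connectome} (after all removals) and
#'   \code{removed}, a data.frame with columns step, i, j (1-based node
#'   indices), label_i, label_j, weight.
#' @export
perturbEdges <- function(x, nEdges) {
  stopifnot(is(x, "Connectome"))
  el <- .edgeList(weightMatrix(x))
  if (nEdges > nrow(el)) {
    stop(sprintf("nEdges (%d) exceeds edge count (%d)", nEdges, nrow(el)))
  }
  pick <- sample(nrow(el), nEdges)
  removed <- el[pick, , drop = FALSE]
  removed$step <- seq_len(nEdges)
  removed$label_i <- x@labels[removed$i]
  removed$label_j <- x@labels[removed$j]
  W <- weightMatrix(x)
  W[cbind(removed$i, removed$j)] <- 0
  W[cbind(removed$j, removed$i)] <- 0
  rownames(removed) <- NULL
  list(connectome = setWeights(x, W),
       removed = removed[, c("step", "i", "j", "label_i", "label_j", "w")])
}

#' Select lesion target nodes for every subject of a cohort
#'
#' Target modes:
#' \describe{
#'   \item{hubs_shared}{one shared list for all subjects: hubs of the
#'     requested hemisphere in the cohort's average network, ordered by
#'     descending degree; its length is the median per-scan hub count in
#'     that hemisphere (rounded down), unless \code{nTargets} overrides
#'     it.}
#'   \item{random_shared}{one uniform draw from the hemisphere's nodes,
#'     reused for every subject.}
#'   \item{random_individual}{an independent draw per subject, from
#'     subject-specific RNG streams derived from \code{seed}.}
#'   \item{fixed_list}{the given node labels, shared.}
#' }
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param mode one of the four modes above.
#' @param hemisphere hemisphere restriction, default \code{"R"}; \code{NULL}
#'   allows the whole network.
#' @param nTargets number of targets; default (NULL) uses the median hub
#'   count rule for \code{hubs_shared} and is required otherwise.
#' @param seed root seed for the random modes.
#' @param fixed node labels for \code{fixed_list}.
#' @param presenceThreshold consensus threshold for the average network.
#' @return Named list (one element per subject) of integer node-index
#'   vectors.
#' @export
selectTargets <- function(cohort, mode = c("hubs_shared", "random_shared",
                                           "random_individual", "fixed_list"),
                          hemisphere = "R", nTargets = NULL, seed = 1L,
                          fixed = NULL, presenceThreshold = 0.75) {
  stopifnot(is(cohort, "Cohort"))
  mode <- match.arg(mode)
  ref <- cohort@scanA[[1]]
  pool <- if (is.null(hemisphere)) {
    seq_len(nNodes(ref))
  } else {
    which(ref@hemisphere == hemisphere)
  }
  ids <- subjectIds(cohort)
  shared_list <- function(targets) {
    stats::setNames(rep(list(targets), length(ids)), ids)
  }
  if (mode == "fixed_list") {
    if (is.null(fixed)) stop("fixed_list mode requires 'fixed' labels")
    return(shared_list(.resolveNodes(fixed, ref@labels)))
  }
  if (mode == "hubs_shared") {
    avg <- buildAverageNetwork(cohort, presenceThreshold = presenceThreshold)
    hubs <- identifyHubs(avg, hemisphere = hemisphere)
    if (is.null(nTargets)) {
      counts <- vapply(c(cohort@scanA, cohort@scanB),
                       function(s) length(identifyHubs(s, hemisphere = hemisphere)),
                       numeric(1))
      nTargets <- floor(stats::median(counts))
    }
    deg <- degreeStrength(avg)$degree
    hubs <- hubs[order(-deg[hubs], hubs)]
    if (length(hubs) < nTargets) {
      stop(sprintf("only %d hubs available for %d targets",
                   length(hubs), nTargets))
    }
    return(shared_list(hubs[seq_len(nTargets)]))
  }
  if (is.null(nTargets)) stop("random modes require nTargets")
  if (length(pool) < nTargets) stop("insufficient nodes in hemisphere")
  if (mode == "random_shared") {
    set.seed(deriveSeed(seed, "targets", "shared"))
    return(shared_list(sort(sample(pool, nTargets))))
  }
  ## random_individual: one derived stream per subject
  out <- lapply(seq_along(ids), function(k) {
    set.seed(deriveSeed(seed, "targets", ids[k]))
    sort(sample(pool, nTargets))
  })
  stats::setNames(out, ids)
}
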