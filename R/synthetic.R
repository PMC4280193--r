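#' Construct a CohortSpec for the synthetic two-scan generator
#'
#' Defaults emulate the kind of cohort the analyses assume: 19 subjects,
#' an 86-node bihemispheric parcellation, a consensus backbone of density
#' 0.20 with heavy-tailed (log-normal) positive weights, designated hub
#' nodes wired at about three times the baseline connection probability,
#' and two scans per subject that differ only by mean-one multiplicative
#' weight noise (log-sd 0.1) plus a 1\% chance per edge of flipping
#' presence between scans — measurement noise, not biology, so baseline
#' group comparisons are null.
#'
#' @param nSubjects number of subjects (default 19).
#' @param nNodes even node count, half per hemisphere (default 86).
#' @param edgeDensity target backbone density (default 0.20).
#' @param weightMeanlog,weightSdlog log-normal weight parameters
#'   (default 0 and 1: right-skewed, positive).
#' @param hubFraction fraction of nodes per hemisphere designated hubs
#'   (default 0.12).
#' @param hubMultiplier connection-probability multiplier for hub
#'   endpoints (default 3).
#' @param interHemFraction target fraction of edges crossing hemispheres
#'   (default 0.15).
#' @param scanNoiseSd log-sd of the between-scan multiplicative weight
#'   noise (default 0.1); the noise factor has mean one.
#' @param edgeJitterProb probability an edge flips presence between scans
#'   (default 0.01).
#' @param subjectEdgeProb probability a backbone edge is realized in a
#'   subject (default 0.9, so backbone edges pass a 75\% consensus rule).
#' @param subjectSdlog log-sd of per-subject weight deviations from the
#'   group edge weight (default 0.2).
#' @param seed root RNG seed.
#' @return A validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 19L, nNodes = 86L, edgeDensity = 0.20,
                       weightMeanlog = 0, weightSdlog = 1,
                       hubFraction = 0.12, hubMultiplier = 3,
                       interHemFraction = 0.15, scanNoiseSd = 0.1,
                       edgeJitterProb = 0.01, subjectEdgeProb = 0.9,
                       subjectSdlog = 0.2, seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      nNodes = as.integer(nNodes), edgeDensity = edgeDensity,
      weightMeanlog = weightMeanlog, weightSdlog = weightSdlog,
      hubFraction = hubFraction, hubMultiplier = hubMultiplier,
      interHemFraction = interHemFraction, scanNoiseSd = scanNoiseSd,
      edgeJitterProb = edgeJitterProb, subjectEdgeProb = subjectEdgeProb,
      subjectSdlog = subjectSdlog, seed = as.integer(seed))
}

## node metadata for the synthetic parcellation: two lateralized clusters
## with named subcortical nodes so the stroke preset runs unmodified
.syntheticNodes <- function(n) {
  half <- n / 2
  hemi <- rep(c("L", "R"), each = half)
  labels <- character(n)
  labels[1] <- "Left-Thalamus"
  labels[2] <- "Left-Caudate"
  labels[half + 1] <- "Right-Thalamus"
  labels[half + 2] <- "Right-Caudate"
  labels[3:half] <- paste0("ctx-lh-roi", seq_len(half - 2))
  labels[(half + 3):n] <- paste0("ctx-rh-roi", seq_len(half - 2))
  list(labels = labels, hemisphere = hemi, half = half)
}

#' Generate a synthetic two-scan cohort
#'
#' Generative model: nodes are placed on two lateralized coordinate
#' clusters; a group-level backbone edge set is drawn with
#' distance-decaying connection probabilities, scaled to the target
#' density, with hub endpoints upweighted by \code{hubMultiplier} and
#' cross-hemisphere pairs scaled to the target inter-hemispheric edge
#' fraction. Each subject's first scan realizes every backbone edge with
#' probability \code{subjectEdgeProb} (plus a small spurious-edge rate),
#' weighting it by the group's log-normal edge weight times a per-subject
#' log-normal deviation. The second scan multiplies every weight by
#' mean-one log-normal noise and applies presence flicker: with
#' probability \code{edgeJitterProb}, a weak edge slot (bottom quartile of
#' backbone weights, or spurious) redraws its presence from the same
#' inclusion law as the first scan. Restricting flicker to
#' near-detection-threshold connections mirrors test-retest tractography
#' noise — strong tracts do not vanish between sessions — and the
#' redraw makes the two scans exchangeable (identical marginals, no
#' systematic edge loss), so baseline group comparisons are null by
#' construction. Identical spec and seed give a bit-identical cohort.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return A \linkS4class{Cohort}; its attributes \code{"hubs"} and
#'   \code{"backbone"} record the designated hub indices and the backbone
#'   edge matrix for parameter-recovery tests.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nNodes
  meta <- .syntheticNodes(n)
  half <- meta$half
  set.seed(deriveSeed(spec@seed, "backbone"))
  coords <- cbind(x = ifelse(meta$hemisphere == "L", -30, 30) +
                    stats::rnorm(n, 0, 8),
                  y = stats::rnorm(n, 0, 20),
                  z = stats::rnorm(n, 0, 15))
  nHubs <- max(1L, round(spec@hubFraction * half))
  hubs <- c(seq_len(nHubs), half + seq_len(nHubs))  # subcortical nodes first
  if (spec@hubMultiplier * max(1, nHubs) > n - 1) stop("infeasible hub degree")

  ## distance-decaying affinity, hub upweighting, cross-hemisphere scaling
  D <- as.matrix(stats::dist(coords))
  aff <- exp(-D / stats::median(D))
  isHub <- seq_len(n) %in% hubs
  hubPair <- outer(isHub, isHub, "|")
  aff[hubPair] <- aff[hubPair] * spec@hubMultiplier
  cross <- outer(meta$hemisphere, meta$hemisphere, "!=")
  upper <- upper.tri(aff)
  curCross <- sum(aff[upper & cross]) / sum(aff[upper])
  if (curCross > 0 && curCross < 1) {
    f <- spec@interHemFraction / curCross *
      (1 - curCross) / (1 - spec@interHemFraction)
    aff[cross] <- aff[cross] * f
  }
  nPairs <- n * (n - 1) / 2
  P <- aff * (spec@edgeDensity * nPairs / sum(aff[upper]))
  P[P > 0.95] <- 0.95
  backbone <- matrix(FALSE, n, n)
  backbone[upper] <- stats::runif(nPairs) < P[upper]
  backbone <- backbone | t(backbone)
  Wgroup <- matrix(0, n, n)
  Wgroup[upper][backbone[upper]] <-
    stats::rlnorm(sum(backbone[upper]), spec@weightMeanlog, spec@weightSdlog)
  Wgroup <- Wgroup + t(Wgroup)

  ids <- sprintf("subj%02d", seq_len(spec@nSubjects))
  scanAList <- vector("list", spec@nSubjects)
  scanBList <- vector("list", spec@nSubjects)
  spuriousProb <- 0.01
  for (k in seq_len(spec@nSubjects)) {
    set.seed(deriveSeed(spec@seed, "subject", ids[k]))
    keep <- backbone[upper] & (stats::runif(nPairs) < spec@subjectEdgeProb)
    spurious <- !backbone[upper] & (stats::runif(nPairs) < spuriousProb)
    wA <- numeric(nPairs)
    wA[keep] <- Wgroup[upper][keep] *
      stats::rlnorm(sum(keep), 0, spec@subjectSdlog)
    wA[spurious] <- stats::rlnorm(sum(spurious), spec@weightMeanlog - 1,
                                  spec@weightSdlog)
    WA <- matrix(0, n, n)
    WA[upper] <- wA
    WA <- WA + t(WA)

    ## scan B: mean-one multiplicative noise + presence jitter
    set.seed(deriveSeed(spec@seed, "scanB", ids[k]))
    noise <- stats::rlnorm(nPairs, -spec@scanNoiseSd^2 / 2, spec@scanNoiseSd)
    wB <- wA * noise
    if (spec@edgeJitterProb > 0) {
      ## presence flicker is confined to weak, near-detection-threshold
      ## connections (strong tracts do not vanish between sessions), and
      ## flipped pairs redraw presence from the same inclusion law as scan
      ## A, so the two scans are exchangeable (identical marginals, no
      ## systematic edge loss between sessions)
      gw <- Wgroup[upper]
      weakThr <- stats::quantile(gw[gw > 0], 0.25)
      eligible <- !backbone[upper] | (gw > 0 & gw <= weakThr)
      flip <- eligible & stats::runif(nPairs) < spec@edgeJitterProb
      inclProb <- ifelse(backbone[upper], spec@subjectEdgeProb, spuriousProb)
      present <- stats::runif(nPairs) < inclProb
      dropIdx <- flip & !present & wB > 0
      reviveIdx <- flip & present & wB == 0
      wB[dropIdx] <- 0
      wB[reviveIdx & backbone[upper]] <-
        Wgroup[upper][reviveIdx & backbone[upper]] *
        stats::rlnorm(sum(reviveIdx & backbone[upper]), 0, spec@subjectSdlog)
      wB[reviveIdx & !backbone[upper]] <-
        stats::rlnorm(sum(reviveIdx & !backbone[upper]),
                      spec@weightMeanlog - 1, spec@weightSdlog)
    }
    WB <- matrix(0, n, n)
    WB[upper] <- wB
    WB <- WB + t(WB)

    scanAList[[k]] <- Connectome(WA, labels = meta$labels,
                                 hemisphere = meta$hemisphere, coords = coords)
    scanBList[[k]] <- Connectome(WB, labels = meta$labels,
                                 hemisphere = meta$hemisphere, coords = coords)
  }
  out <- Cohort(ids, scanAList, scanBList, atlasName = "synthetic-bihemispheric")
  attr(out, "hubs") <- hubs
  attr(out, "backbone") <- backbone
  out
}

#' Inject a distance-decaying lesion effect into scan B
#'
#' Ground-truth generator for change-versus-distance recovery tests: in
#' every subject's second scan, node i's incident weights are scaled by
#' \code{1 - amplitude * exp(-decayRate * d_i)} where \code{d_i} is the
#' binary hop distance of node i from the focus on that scan (focus nodes
#' have d = 0). Edge (i, j) receives both endpoint factors. With
#' \code{amplitude = 1} the focus nodes are disconnected outright (so
#' binary metrics also change); smaller amplitudes leave the topology
#' intact and only dampen weights.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param focusNodes node indices or labels of the lesion focus.
#' @param amplitude effect size at distance 0, in [0, 1].
#' @param decayRate exponential decay rate per hop (> 0).
#' @return The modified \linkS4class{Cohort}.
#' @export
injectDistanceDecayingEffect <- function(cohort, focusNodes, amplitude,
                                         decayRate) {
  stopifnot(is(cohort, "Cohort"), amplitude >= 0, amplitude <= 1,
            decayRate > 0)
  if (amplitude == 0) return(cohort)
  ref <- cohort@scanA[[1]]
  focus <- .resolveNodes(focusNodes, ref@labels)
  for (k in seq_len(nSubjects(cohort))) {
    con <- cohort@scanB[[k]]
    d <- distanceFromLesion(con, focus, kind = "binary")
    fac <- 1 - amplitude * exp(-decayRate * d)
    fac[!is.finite(d)] <- 1
    W <- weightMatrix(con) * outer(fac, fac)
    cohort@scanB[[k]] <- setWeights(con, W)
  }
  cohort
}
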