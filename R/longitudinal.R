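## Two-scan longitudinal lesion experiments
## ----------------------------------------
## Each subject has two scans differing only by measurement noise. A
## seeded coin flip decides which scan is the baseline; the other scan
## receives the simulated lesions, so baseline-vs-lesioned comparisons
## carry realistic test-retest noise, as in a longitudinal patient study.

.applyNodeLesion <- function(x, node, kind, rate) {
  switch(kind,
         node_binary = perturbNodeBinary(x, node, rate),
         node_weighted = perturbNodeWeighted(x, node, rate),
         node_removal = perturbNodeWeighted(x, node, 1))
}

#' Run a longitudinal lesion experiment on a two-scan cohort
#'
#' For every subject one scan (seeded coin flip) becomes the baseline and
#' the other receives the lesion sequence. Lesions are applied
#' cumulatively — after step k, targets 1..k have been lesioned (node
#' kinds) or k edges removed (\code{edge_removal}) — and the lesioned
#' networks at every requested step are retained for the statistics
#' layer. Repetitions rerun the whole procedure with fresh random target
#' draws from repetition-specific RNG streams.
#'
#' For \code{edge_removal} with a shared target mode the edge sequence is
#' drawn from the cohort's average network, so the same anatomical
#' connections are removed in every subject (removals of edges a subject
#' lacks are no-ops); with \code{random_individual} each subject's edges
#' are drawn from its own lesion scan.
#'
#' @param cohort a \linkS4class{Cohort}; every subject needs both scans.
#' @param spec a \linkS4class{LesionSpec}.
#' @param evalSteps lesion steps at which the lesioned state is retained;
#'   default \code{1:N} for node kinds and \code{1:Ne} for edges.
#' @param targets optional precomputed per-subject target list (overrides
#'   \code{spec@targetMode}).
#' @return List with elements \code{spec}, \code{baselineIsScanA}
#'   (logical per subject), \code{baseline} and \code{prelesion} (lists of
#'   \linkS4class{Connectome}), and \code{repetitions}: one element per
#'   repetition holding \code{targets} (or \code{edgeDraws}),
#'   \code{evalSteps} and \code{states}, a list over steps of per-subject
#'   lesioned connectomes.
#' @export
runLongitudinalExperiment <- function(cohort, spec, evalSteps = NULL,
                                      targets = NULL) {
  stopifnot(is(cohort, "Cohort"), is(spec, "LesionSpec"))
  ids <- subjectIds(cohort)
  ns <- length(ids)
  if (ns == 0) stop("empty cohort")
  set.seed(deriveSeed(spec@seed, "baseline-assignment"))
  baselineIsScanA <- stats::runif(ns) < 0.5
  baseline <- vector("list", ns)
  prelesion <- vector("list", ns)
  for (k in seq_len(ns)) {
    baseline[[k]] <- if (baselineIsScanA[k]) cohort@scanA[[k]] else cohort@scanB[[k]]
    prelesion[[k]] <- if (baselineIsScanA[k]) cohort@scanB[[k]] else cohort@scanA[[k]]
  }
  names(baseline) <- names(prelesion) <- ids

  nSteps <- if (spec@kind == "edge_removal") spec@nEdges else spec@nTargets
  if (is.null(evalSteps)) evalSteps <- seq_len(nSteps)
  evalSteps <- sort(unique(as.integer(evalSteps)))
  stopifnot(all(evalSteps >= 0), all(evalSteps <= nSteps))

  hemi <- if (is.na(spec@hemisphere)) NULL else spec@hemisphere
  reps <- vector("list", spec@repetitions)
  for (r in seq_len(spec@repetitions)) {
    repSeed <- deriveSeed(spec@seed, "rep", r)
    repTargets <- NULL
    edgeDraws <- NULL
    if (spec@kind == "edge_removal") {
      shared <- spec@targetMode != "random_individual"
      edgeDraws <- vector("list", ns)
      if (shared) {
        avg <- buildAverageNetwork(cohort)
        set.seed(deriveSeed(repSeed, "edges", "shared"))
        el <- .edgeList(weightMatrix(avg))
        if (spec@nEdges > nrow(el)) stop("nEdges exceeds average-network edge count")
        pick <- el[sample(nrow(el), spec@nEdges), c("i", "j"), drop = FALSE]
        for (k in seq_len(ns)) edgeDraws[[k]] <- pick
      } else {
        for (k in seq_len(ns)) {
          set.seed(deriveSeed(repSeed, "edges", ids[k]))
          el <- .edgeList(weightMatrix(prelesion[[k]]))
          if (spec@nEdges > nrow(el)) stop("nEdges exceeds subject edge count")
          edgeDraws[[k]] <- el[sample(nrow(el), spec@nEdges), c("i", "j"),
                               drop = FALSE]
        }
      }
      names(edgeDraws) <- ids
    } else if (!is.null(targets)) {
      repTargets <- targets
    } else {
      repTargets <- selectTargets(
        cohort,
        mode = spec@targetMode,
        hemisphere = hemi,
        nTargets = if (spec@nTargets > 0) spec@nTargets else NULL,
        seed = deriveSeed(repSeed, "targets"),
        fixed = if (length(spec@fixedTargets)) spec@fixedTargets else NULL)
    }

    states <- vector("list", length(evalSteps))
    names(states) <- paste0("step", evalSteps)
    current <- prelesion
    lastStep <- 0L
    for (si in seq_along(evalSteps)) {
      s <- evalSteps[si]
      while (lastStep < s) {
        lastStep <- lastStep + 1L
        for (k in seq_len(ns)) {
          if (spec@kind == "edge_removal") {
            e <- edgeDraws[[k]][lastStep, ]
            W <- weightMatrix(current[[k]])
            W[e$i, e$j] <- 0
            W[e$j, e$i] <- 0
            current[[k]] <- setWeights(current[[k]], W)
          } else {
            node <- repTargets[[k]][lastStep]
            deg <- sum(weightMatrix(current[[k]])[node, ] > 0)
            if (spec@kind == "node_binary" && deg == 0) next  # already isolated
            set.seed(deriveSeed(repSeed, "lesion", ids[k], lastStep))
            current[[k]] <- .applyNodeLesion(current[[k]], node, spec@kind,
                                             spec@rate)
          }
        }
      }
      states[[si]] <- current
    }
    reps[[r]] <- list(targets = repTargets, edgeDraws = edgeDraws,
                      evalSteps = evalSteps, states = states)
  }
  list(spec = spec, baselineIsScanA = baselineIsScanA, baseline = baseline,
       prelesion = prelesion, repetitions = reps)
}

#' Subjects-by-nodes matrix of one metric over a list of connectomes
#'
#' @param connectomes list of \linkS4class{Connectome} sharing node order.
#' @param metric metric name (see \code{\link{nodeMetric}}).
#' @return Numeric matrix, one row per connectome, one column per node.
#' @export
metricArray <- function(connectomes, metric) {
  t(vapply(connectomes, function(x) unname(nodeMetric(x, metric)),
           numeric(nNodes(connectomes[[1]]))))
}

#' Simulated stroke preset: lesions to the left thalamus and caudate
#'
#' Applies weighted and binary node lesions at the two fixed subcortical
#' sites, with a per-subject lesion rate drawn uniformly from
#' \code{rateRange}, repeated \code{repetitions} times with fresh rate and
#' connection draws; test statistics are averaged over the repetitions.
#' Outputs compare each subject's lesioned scan with its baseline scan at
#' the global, hemispheric and local (per-node) level.
#'
#' @param cohort a \linkS4class{Cohort} whose labels contain both sites.
#' @param siteLabels labels of the lesion sites (configurable mapping).
#' @param rateRange range of the uniform per-subject lesion rate.
#' @param repetitions number of repetitions to average (default 10).
#' @param seed root RNG seed.
#' @param alpha FDR-corrected significance level.
#' @param metrics node metrics to analyze.
#' @return List with \code{global} (per metric and lesion kind: mean
#'   change and paired-t p), \code{hemispheric} (the same split by L/R),
#'   \code{local} (per metric and kind: per-node mean change, mean t,
#'   mean FDR-adjusted p over repetitions, significance fraction), the
#'   lesioned \code{sites}, and \code{seed}.
#' @export
strokePreset <- function(cohort, siteLabels = c("Left-Thalamus", "Left-Caudate"),
                         rateRange = c(0.2, 0.8), repetitions = 10L, seed = 1L,
                         alpha = 0.05,
                         metrics = c("Deg", "Sw", "BC", "BCw", "Cm", "Cmw",
                                     "CBC", "CBCw")) {
  stopifnot(is(cohort, "Cohort"))
  ref <- cohort@scanA[[1]]
  sites <- .resolveNodes(siteLabels, ref@labels)
  ids <- subjectIds(cohort)
  ns <- length(ids)
  set.seed(deriveSeed(seed, "stroke-baseline"))
  baselineIsScanA <- stats::runif(ns) < 0.5
  baseline <- lapply(seq_len(ns), function(k) {
    if (baselineIsScanA[k]) cohort@scanA[[k]] else cohort@scanB[[k]]
  })
  prelesion <- lapply(seq_len(ns), function(k) {
    if (baselineIsScanA[k]) cohort@scanB[[k]] else cohort@scanA[[k]]
  })

  kinds <- c("node_weighted", "node_binary")
  perRep <- list()
  for (r in seq_len(repetitions)) {
    set.seed(deriveSeed(seed, "stroke-rates", r))
    rates <- stats::runif(ns, rateRange[1], rateRange[2])
    for (kind in kinds) {
      lesioned <- vector("list", ns)
      for (k in seq_len(ns)) {
        cur <- prelesion[[k]]
        for (s in sites) {
          if (kind == "node_binary" &&
              sum(weightMatrix(cur)[s, ] > 0) == 0) next
          set.seed(deriveSeed(seed, "stroke-lesion", r, kind, ids[k], s))
          cur <- .applyNodeLesion(cur, s, kind, rates[k])
        }
        lesioned[[k]] <- cur
      }
      perRep[[paste(kind, r, sep = ".")]] <-
        list(kind = kind, rep = r, lesioned = lesioned, rates = rates)
    }
  }

  globalRows <- list()
  hemiRows <- list()
  localTabs <- list()
  for (kind in kinds) {
    entries <- Filter(function(e) e$kind == kind, perRep)
    for (m in metrics) {
      base <- metricArray(baseline, m)
      gl <- numeric(0); glp <- numeric(0)
      hemiL <- numeric(0); hemiLp <- numeric(0)
      hemiR <- numeric(0); hemiRp <- numeric(0)
      nodeChange <- 0; nodeT <- 0; nodeP <- 0; sigCount <- 0
      for (e in entries) {
        les <- metricArray(e$lesioned, m)
        gB <- rowMeans(base); gL <- rowMeans(les)
        tt <- .pairedT(gB, gL)
        gl <- c(gl, mean(gB - gL)); glp <- c(glp, tt$p)
        isL <- ref@hemisphere == "L"; isR <- ref@hemisphere == "R"
        tL <- .pairedT(rowMeans(base[, isL, drop = FALSE]),
                       rowMeans(les[, isL, drop = FALSE]))
        tR <- .pairedT(rowMeans(base[, isR, drop = FALSE]),
                       rowMeans(les[, isR, drop = FALSE]))
        hemiL <- c(hemiL, mean(base[, isL]) - mean(les[, isL]))
        hemiLp <- c(hemiLp, tL$p)
        hemiR <- c(hemiR, mean(base[, isR]) - mean(les[, isR]))
        hemiRp <- c(hemiRp, tR$p)
        rep_report <- changeReport(base, les, alpha = alpha,
                                   labels = ref@labels)
        nodeChange <- nodeChange + rep_report$meanChange
        nodeT <- nodeT + ifelse(is.finite(rep_report$t), rep_report$t, 0)
        nodeP <- nodeP + rep_report$pAdj
        sigCount <- sigCount + rep_report$significant
      }
      nr <- length(entries)
      globalRows[[paste(kind, m)]] <- data.frame(
        kind = kind, metric = m, meanChange = mean(gl), meanP = mean(glp),
        stringsAsFactors = FALSE)
      hemiRows[[paste(kind, m)]] <- data.frame(
        kind = kind, metric = m,
        ipsiChange = mean(hemiL), ipsiP = mean(hemiLp),
        contraChange = mean(hemiR), contraP = mean(hemiRp),
        stringsAsFactors = FALSE)
      localTabs[[paste(kind, m)]] <- data.frame(
        kind = kind, metric = m, index = seq_len(nNodes(ref)),
        label = ref@labels, hemisphere = ref@hemisphere,
        meanChange = nodeChange / nr, meanT = nodeT / nr,
        meanPAdj = nodeP / nr, sigFraction = sigCount / nr,
        stringsAsFactors = FALSE)
    }
  }
  list(global = do.call(rbind, c(globalRows, make.row.names = FALSE)),
       hemispheric = do.call(rbind, c(hemiRows, make.row.names = FALSE)),
       local = do.call(rbind, c(localTabs, make.row.names = FALSE)),
       sites = sites, siteLabels = siteLabels, repetitions = repetitions,
       seed = seed)
}
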