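## Experiment pipelines
## --------------------
## Each runner takes a resolved config (plain named list), derives every
## random draw from config$seed, returns a report bundle embedding the
## config, and optionally writes diff-able TSV/JSON artifacts. Re-running
## a bundle's config reproduces the bundle bit-identically.

.resolveCohort <- function(config) {
  if (!is.null(config$cohort)) return(config$cohort)
  if (!is.null(config$manifest)) return(readCohort(config$manifest))
  if (!is.null(config$cohortSpec)) {
    sp <- config$cohortSpec
    if (is(sp, "CohortSpec")) return(generateCohort(sp))
    return(generateCohort(do.call(cohortSpec, sp)))
  }
  stop("config must provide 'cohort', 'manifest' or 'cohortSpec'")
}

.writeBundleJSON <- function(summary, outDir, name) {
  jsonlite::write_json(summary, file.path(outDir, name), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

#' Run the targeted-attack strategy comparison
#'
#' For every criterion and selection method, runs a targeted attack on
#' each subject's first scan, collects the binary and weighted efficiency
#' decay curves, compares strategy pairs with the curve permutation test,
#' and runs paired t-tests on efficiency at the checkpoint steps.
#'
#' Config fields (with defaults): \code{cohort}/\code{cohortSpec}/
#' \code{manifest}; \code{criteria} (default \code{c("Deg", "BC", "Cm",
#' "CBC")}); \code{methods} (both); \code{nAttacks} (80);
#' \code{nPerm} (5000); \code{checkpoints} (\code{c(10, 20, 40, 80)},
#' clipped to nAttacks); \code{weightedEff} — which efficiency feeds the
#' tests (\code{"binary"} default); \code{seed} (1).
#'
#' @param config named list, see above.
#' @param outDir optional output directory for TSV/JSON artifacts.
#' @return Report bundle: list with \code{config}, \code{curves} (per
#'   strategy, subjects-by-steps efficiency matrices, intact value
#'   first), \code{meanCurves}, \code{permutation} (data.frame of
#'   pairwise strategy tests), and \code{checkpointTests}.
#' @export
runTargetedAttacks <- function(config, outDir = NULL) {
  cohort <- .resolveCohort(config)
  criteria <- config$criteria %||% c("Deg", "BC", "Cm", "CBC")
  methods <- config$methods %||% c("single_choice", "hubs_order")
  nAttacks <- config$nAttacks %||% 80L
  nPerm <- config$nPerm %||% 5000L
  checkpoints <- config$checkpoints %||% c(10L, 20L, 40L, 80L)
  checkpoints <- checkpoints[checkpoints <= nAttacks]
  useWeighted <- identical(config$weightedEff %||% "binary", "weighted")
  seed <- config$seed %||% 1L
  config <- list(criteria = criteria, methods = methods, nAttacks = nAttacks,
                 nPerm = nPerm, checkpoints = checkpoints,
                 weightedEff = if (useWeighted) "weighted" else "binary",
                 seed = seed, cohort = cohort)

  nets <- cohort@scanA
  strategies <- expand.grid(criterion = criteria, method = methods,
                            stringsAsFactors = FALSE)
  stratKeys <- make.unique(paste(strategies$criterion, strategies$method,
                                 sep = "-"))
  curves <- list()
  for (i in seq_len(nrow(strategies))) {
    cr <- strategies$criterion[i]
    me <- strategies$method[i]
    mat <- do.call(rbind, lapply(nets, function(net) {
      tr <- targetedAttack(net, criterion = cr, method = me,
                           nAttacks = min(nAttacks, nNodes(net) - 1L))
      eff <- if (useWeighted) tr@effWeighted else tr@effBinary
      length(eff) <- nAttacks + 1L          # pad truncated traces with NA
      eff
    }))
    curves[[stratKeys[i]]] <- mat
  }
  meanCurves <- lapply(curves, colMeans)

  keys <- names(curves)
  permRows <- list()
  pi <- 0L
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (b <= a) next
      pi <- pi + 1L
      pt <- permutationTestCurves(curves[[keys[a]]], curves[[keys[b]]],
                                  nPerm = nPerm,
                                  seed = deriveSeed(seed, "perm", keys[a],
                                                    keys[b]))
      permRows[[pi]] <- data.frame(strategyA = keys[a], strategyB = keys[b],
                                   statistic = pt$statistic, p = pt$p,
                                   stringsAsFactors = FALSE)
    }
  }
  permutation <- if (length(permRows)) {
    do.call(rbind, c(permRows, make.row.names = FALSE))
  } else {
    data.frame()
  }

  cpRows <- list()
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (b <= a) next
      for (s in checkpoints) {
        tt <- .pairedT(curves[[keys[a]]][, s + 1L], curves[[keys[b]]][, s + 1L])
        cpRows[[length(cpRows) + 1L]] <- data.frame(
          strategyA = keys[a], strategyB = keys[b], step = s,
          t = tt$t, p = tt$p, stringsAsFactors = FALSE)
      }
    }
  }
  checkpointTests <- if (length(cpRows)) {
    do.call(rbind, c(cpRows, make.row.names = FALSE))
  } else {
    data.frame()
  }

  bundle <- list(config = config, curves = curves, meanCurves = meanCurves,
                 permutation = permutation, checkpointTests = checkpointTests)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    mc <- data.frame(step = 0:nAttacks, lapply(meanCurves, identity),
                     check.names = FALSE)
    .writeTSV(mc, file.path(outDir, "mean_curves.tsv"))
    .writeTSV(permutation, file.path(outDir, "permutation_tests.tsv"))
    .writeTSV(checkpointTests, file.path(outDir, "checkpoint_ttests.tsv"))
    .writeBundleJSON(list(experiment = "targeted_attacks", seed = seed,
                          criteria = criteria, methods = methods,
                          nAttacks = nAttacks, nPerm = nPerm),
                     outDir, "summary.json")
  }
  bundle
}

#' Run the small-perturbation longitudinal experiment
#'
#' Applies a lesion specification to the two-scan cohort, computes
#' per-step change reports for the requested metrics, sensitivity
#' summaries (significant-change counts and earliest change), the
#' change-versus-distance correlation table at the final step, and the
#' change-location ranking across repetitions.
#'
#' Config fields: \code{cohort}/\code{cohortSpec}/\code{manifest};
#' \code{lesion} (a \linkS4class{LesionSpec} or argument list for
#' \code{\link{lesionSpec}}); \code{metrics} (default all eight);
#' \code{alpha} (0.05); \code{evalSteps} (default every step);
#' \code{seed} (overrides the lesion spec seed when given).
#'
#' @param config named list, see above.
#' @param outDir optional output directory.
#' @return Bundle with \code{config}, \code{experiment} (raw states),
#'   \code{reports} (per repetition, metric, step), \code{sensitivity},
#'   \code{correlations}, \code{locations}.
#' @export
runSmallPerturbations <- function(config, outDir = NULL) {
  cohort <- .resolveCohort(config)
  spec <- config$lesion %||% lesionSpec()
  if (!is(spec, "LesionSpec")) spec <- do.call(lesionSpec, spec)
  if (!is.null(config$seed)) spec@seed <- as.integer(config$seed)
  metrics <- config$metrics %||% .metricNames
  alpha <- config$alpha %||% 0.05
  config <- list(lesion = spec, metrics = metrics, alpha = alpha,
                 evalSteps = config$evalSteps, seed = spec@seed,
                 cohort = cohort)

  exper <- runLongitudinalExperiment(cohort, spec,
                                     evalSteps = config$evalSteps)
  ref <- cohort@scanA[[1]]
  baseArrays <- lapply(stats::setNames(metrics, metrics), function(m) {
    metricArray(exper$baseline, m)
  })

  reports <- list()      # reports[[rep]][[metric]][[step]]
  sensitivity <- list()
  for (r in seq_along(exper$repetitions)) {
    repData <- exper$repetitions[[r]]
    reports[[r]] <- list()
    for (m in metrics) {
      reports[[r]][[m]] <- lapply(repData$states, function(state) {
        changeReport(baseArrays[[m]], metricArray(state, m), alpha = alpha,
                     labels = ref@labels)
      })
      lesioned <- if (spec@kind == "edge_removal") NULL else repData$targets[[1]]
      sensitivity[[paste(m, r, sep = ".")]] <- c(
        list(metric = m, repetition = r),
        sensitivitySummary(reports[[r]][[m]], excludeNodes = lesioned))
    }
  }

  ## change-vs-distance at the final step, averaged over repetitions via
  ## the first repetition's targets (shared modes: identical anyway)
  correlations <- NULL
  if (spec@kind != "edge_removal") {
    lastStep <- length(exper$repetitions[[1]]$states)
    targets1 <- exper$repetitions[[1]]$targets[[1]]
    changes <- lapply(stats::setNames(metrics, metrics), function(m) {
      baseArrays[[m]] - metricArray(exper$repetitions[[1]]$states[[lastStep]], m)
    })
    dists <- list(
      DistW = t(vapply(exper$baseline, function(x) {
        distanceFromLesion(x, targets1, "weighted")
      }, numeric(nNodes(ref)))),
      DistB = t(vapply(exper$baseline, function(x) {
        distanceFromLesion(x, targets1, "binary")
      }, numeric(nNodes(ref)))))
    if (!is.null(nodeCoords(ref))) {
      dists$DistE <- t(vapply(exper$baseline, function(x) {
        distanceFromLesion(x, targets1, "euclidean")
      }, numeric(nNodes(ref))))
    }
    correlations <- distanceCorrelationTable(changes, dists,
                                             lesionNodes = targets1)
  }

  locations <- list()
  for (m in metrics) {
    finals <- lapply(seq_along(reports), function(r) {
      reps <- reports[[r]][[m]]
      reps[[length(reps)]]
    })
    damaged <- if (spec@kind == "edge_removal") {
      NULL
    } else {
      unique(unlist(lapply(exper$repetitions, function(rp) rp$targets[[1]])))
    }
    locations[[m]] <- reportChangeLocations(finals, damagedNodes = damaged)
  }

  bundle <- list(config = config, experiment = exper, reports = reports,
                 sensitivity = sensitivity, correlations = correlations,
                 locations = locations)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    sens <- do.call(rbind, lapply(sensitivity, function(s) {
      data.frame(metric = s$metric, repetition = s$repetition,
                 totalSignificant = s$totalSignificant,
                 earliestStep = s$earliestStep, stringsAsFactors = FALSE)
    }))
    .writeTSV(sens, file.path(outDir, "sensitivity.tsv"))
    if (!is.null(correlations)) {
      .writeTSV(correlations, file.path(outDir, "distance_correlations.tsv"))
    }
    for (m in names(locations)) {
      if (nrow(locations[[m]])) {
        .writeTSV(locations[[m]],
                  file.path(outDir, sprintf("locations_%s.tsv", m)))
      }
    }
    .writeBundleJSON(list(experiment = "small_perturbations",
                          kind = spec@kind, targetMode = spec@targetMode,
                          rate = spec@rate, nTargets = spec@nTargets,
                          nEdges = spec@nEdges,
                          repetitions = spec@repetitions, seed = spec@seed,
                          alpha = alpha),
                     outDir, "summary.json")
  }
  bundle
}

#' Run the simulated-stroke experiment
#'
#' Thin orchestration over \code{\link{strokePreset}}: resolves the
#' cohort, runs the preset, and writes the global, hemispheric and local
#' comparison tables.
#'
#' Config fields: \code{cohort}/\code{cohortSpec}/\code{manifest};
#' \code{siteLabels} (default left thalamus and caudate);
#' \code{rateRange} (\code{c(0.2, 0.8)}); \code{repetitions} (10);
#' \code{alpha} (0.05); \code{metrics}; \code{seed} (1).
#'
#' @param config named list, see above.
#' @param outDir optional output directory.
#' @return The \code{\link{strokePreset}} result with \code{config}
#'   attached.
#' @export
runStrokePreset <- function(config, outDir = NULL) {
  cohort <- .resolveCohort(config)
  res <- strokePreset(
    cohort,
    siteLabels = config$siteLabels %||% c("Left-Thalamus", "Left-Caudate"),
    rateRange = config$rateRange %||% c(0.2, 0.8),
    repetitions = config$repetitions %||% 10L,
    seed = config$seed %||% 1L,
    alpha = config$alpha %||% 0.05,
    metrics = config$metrics %||% .metricNames)
  res$config <- list(siteLabels = res$siteLabels,
                     repetitions = res$repetitions, seed = res$seed,
                     cohort = cohort)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(res$global, file.path(outDir, "stroke_global.tsv"))
    .writeTSV(res$hemispheric, file.path(outDir, "stroke_hemispheric.tsv"))
    .writeTSV(res$local, file.path(outDir, "stroke_local.tsv"))
    .writeBundleJSON(list(experiment = "stroke_preset",
                          sites = res$siteLabels,
                          repetitions = res$repetitions, seed = res$seed),
                     outDir, "summary.json")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
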