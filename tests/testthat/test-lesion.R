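test_that("targeted attack removes the maximal-criterion node first", {
  ## star: degree criterion removes the center, efficiency collapses to 0
  st <- starGraph(4)
  tr <- targetedAttack(st, criterion = "Deg", method = "single_choice",
                       nAttacks = 1)
  expect_identical(tr@removalOrder, 1L)
  expect_equal(tr@effBinary[1], globalEfficiency(st))
  expect_equal(tr@effBinary[2], 0)

  ## the same holds for any star size (single-choice Deg invariant)
  for (n in c(3, 6, 9)) {
    expect_identical(
      targetedAttack(starGraph(n), "Deg", "single_choice", 1)@removalOrder, 1L)
  }

  ## complete graph stays complete: efficiency 1 after every removal
  trK <- targetedAttack(completeGraph(4), "Sw", "single_choice", nAttacks = 2)
  expect_equal(trK@effBinary, c(1, 1, 1))
  expect_equal(trK@effWeighted[1], trK@effWeighted[1])

  expect_error(targetedAttack(completeGraph(3), "Deg", nAttacks = 3),
               "smaller")
})

test_that("single-choice and hubs-order traces can diverge after step 1", {
  ## search deterministically for a graph whose degree ranking changes
  ## once the first node is removed
  set.seed(91)
  found <- FALSE
  for (i in 1:200) {
    W <- randomConnectedW(7, 0.45)
    con <- Connectome(W)
    a <- targetedAttack(con, "Deg", "single_choice", 3)
    b <- targetedAttack(con, "Deg", "hubs_order", 3)
    if (!identical(a@removalOrder, b@removalOrder)) { found <- TRUE; break }
  }
  expect_true(found)
  expect_identical(a@removalOrder[1], b@removalOrder[1])  # same first pick
})

test_that("binary node perturbation deletes the rounded fraction of edges", {
  ## node with degree 10
  W <- matrix(0, 11, 11); W[1, 2:11] <- W[2:11, 1] <- 1
  con <- Connectome(W)
  set.seed(1)
  expect_equal(sum(weightMatrix(perturbNodeBinary(con, 1, 0.5))[1, ] > 0), 5)
  expect_equal(sum(weightMatrix(perturbNodeBinary(con, 1, 0.8))[1, ] > 0), 2)
  p1 <- perturbNodeBinary(con, 1, 1.0)
  expect_equal(sum(weightMatrix(p1)[1, ]), 0)
  expect_true(isSymmetric(weightMatrix(p1)))
  ## at least one edge goes even at tiny rates
  expect_equal(sum(weightMatrix(perturbNodeBinary(con, 1, 0.01))[1, ] > 0), 9)
  ## isolated node is an error
  W2 <- matrix(0, 3, 3); W2[2, 3] <- W2[3, 2] <- 1
  expect_error(perturbNodeBinary(Connectome(W2), 1, 0.5), "isolated")
})

test_that("weighted node perturbation scales weights, keeping topology", {
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 2; W[1, 3] <- W[3, 1] <- 6
  W[3, 4] <- W[4, 3] <- 1
  con <- Connectome(W)
  p <- perturbNodeWeighted(con, 1, 0.8)
  expect_equal(weightMatrix(p)[1, 2], 0.4)
  expect_equal(weightMatrix(p)[1, 3], 1.2)
  expect_equal(weightMatrix(p)[3, 4], 1)       # untouched elsewhere
  ## binary metrics are blind to weighted lesions below rate 1
  expect_equal(adjacency(p), adjacency(con))
  expect_equal(communicabilityCentrality(p),
               communicabilityCentrality(con))
  ## full rate isolates the node
  expect_equal(sum(weightMatrix(perturbNodeWeighted(con, 1, 1))[1, ]), 0)
})

test_that("edge perturbation removes distinct edges reproducibly", {
  set.seed(5)
  con <- Connectome(randomConnectedW(12, 0.5, weighted = TRUE))
  ne0 <- sum(adjacency(con)) / 2
  set.seed(99)
  res <- perturbEdges(con, 7)
  expect_equal(sum(adjacency(res$connectome)) / 2, ne0 - 7)
  expect_equal(nrow(res$removed), 7)
  expect_false(anyDuplicated(res$removed[, c("i", "j")]) > 0)
  ## same seed, same draw
  set.seed(99)
  res2 <- perturbEdges(con, 7)
  expect_identical(res$removed, res2$removed)
  ## removing every edge empties the graph
  set.seed(1)
  all_gone <- perturbEdges(con, ne0)
  expect_equal(sum(weightMatrix(all_gone$connectome)), 0)
  expect_error(perturbEdges(con, ne0 + 1), "exceeds")
})

test_that("lesion operations preserve connectome invariants and are
           monotone destructive", {
  set.seed(13)
  for (i in 1:10) {
    con <- Connectome(randomConnectedW(10, 0.4, weighted = TRUE))
    W0 <- weightMatrix(con)
    node <- sample(10, 1)
    out <- switch(i %% 3 + 1,
                  perturbNodeBinary(con, node, runif(1, 0.2, 0.8)),
                  perturbNodeWeighted(con, node, runif(1, 0.2, 0.8)),
                  perturbEdges(con, 3)$connectome)
    W1 <- weightMatrix(out)
    expect_true(isSymmetric(W1))
    expect_true(all(diag(W1) == 0))
    expect_true(all(W1 >= 0))
    expect_true(all(W1 <= W0 + 1e-15))       # no weight ever increases
  }
})

test_that("target selection respects mode, hemisphere and RNG streams", {
  co <- tinyCohort(nSubjects = 4, n = 12, seed = 2)
  ## identical networks: hubs mode returns one shared ordered list
  same <- Cohort(c("a", "b"), list(scanA(co, 1), scanA(co, 1)),
                 list(scanA(co, 1), scanA(co, 1)))
  hs <- selectTargets(same, "hubs_shared", hemisphere = "R")
  expect_identical(hs[["a"]], hs[["b"]])
  avg_hubs <- identifyHubs(buildAverageNetwork(same), hemisphere = "R")
  expect_true(all(hs[["a"]] %in% avg_hubs))

  rs <- selectTargets(co, "random_shared", hemisphere = "R", nTargets = 3,
                      seed = 7)
  expect_identical(rs[[1]], rs[[4]])
  expect_true(all(hemispheres(scanA(co, 1))[rs[[1]]] == "R"))

  ri <- selectTargets(co, "random_individual", hemisphere = "R",
                      nTargets = 3, seed = 7)
  ri2 <- selectTargets(co, "random_individual", hemisphere = "R",
                       nTargets = 3, seed = 7)
  expect_identical(ri, ri2)                   # reproducible
  expect_false(all(vapply(ri, identical, logical(1), ri[[1]])))

  fl <- selectTargets(co, "fixed_list", fixed = c("Left-Thalamus",
                                                  "Left-Caudate"))
  expect_identical(fl[[1]], c(1L, 2L))
  expect_error(selectTargets(co, "random_shared", hemisphere = "R",
                             nTargets = 99, seed = 1), "insufficient")
})

test_that("longitudinal experiment assigns baselines and lesions cumulatively", {
  co <- tinyCohort(nSubjects = 4, n = 12, seed = 3)
  spec <- lesionSpec(kind = "node_weighted", targetMode = "random_shared",
                     nTargets = 3, rate = 0.5, repetitions = 2,
                     hemisphere = "R", seed = 11)
  ex <- runLongitudinalExperiment(co, spec)
  expect_length(ex$repetitions, 2)
  expect_length(ex$repetitions[[1]]$states, 3)
  ## baseline + prelesion partition the two scans
  for (k in 1:4) {
    w <- weightMatrix(ex$baseline[[k]]) + weightMatrix(ex$prelesion[[k]])
    expect_equal(w, weightMatrix(scanA(co, k)) + weightMatrix(scanB(co, k)))
  }
  ## strength at lesioned nodes decreases monotonically over steps
  tg <- ex$repetitions[[1]]$targets[[1]]
  s_pre <- metricArray(ex$prelesion, "Sw")[, tg[1]]
  s_1 <- metricArray(ex$repetitions[[1]]$states[[1]], "Sw")[, tg[1]]
  expect_true(all(s_1 < s_pre))
  ## re-running the same spec reproduces the experiment exactly
  ex2 <- runLongitudinalExperiment(co, spec)
  expect_equal(
    weightMatrix(ex$repetitions[[2]]$states[[3]][[2]]),
    weightMatrix(ex2$repetitions[[2]]$states[[3]][[2]]))
  ## zero-lesion spec returns the prelesion scans untouched
  spec0 <- lesionSpec(kind = "node_weighted", targetMode = "fixed_list",
                      fixedTargets = "Left-Thalamus", nTargets = 0L,
                      seed = 11)
  ex0 <- runLongitudinalExperiment(co, spec0, evalSteps = 0)
  expect_equal(weightMatrix(ex0$repetitions[[1]]$states[[1]][[1]]),
               weightMatrix(ex0$prelesion[[1]]))
})

test_that("stroke preset lesions the left subcortical sites", {
  co <- tinyCohort(nSubjects = 4, n = 12, seed = 6)
  res <- strokePreset(co, repetitions = 2, seed = 4,
                      metrics = c("Deg", "Sw"))
  expect_identical(res$sites, c(1L, 2L))
  loc <- res$local
  sw <- loc[loc$metric == "Sw" & loc$kind == "node_weighted", ]
  ## lesioned nodes lose strength (positive change = reduction)
  expect_true(all(sw$meanChange[res$sites] > 0))
  expect_error(strokePreset(co, siteLabels = "NoSuchRegion"), "unknown node")
})
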