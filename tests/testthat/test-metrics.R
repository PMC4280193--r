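test_that("degree and strength count and sum incident edges", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 2.5
  ds <- degreeStrength(Connectome(W))
  expect_equal(unname(ds$degree), c(1, 1))
  expect_equal(unname(ds$strength), c(2.5, 2.5))
  expect_equal(unname(degreeStrength(completeGraph(3))$degree), rep(2, 3))
  ds0 <- degreeStrength(Connectome(matrix(0, 3, 3)))
  expect_equal(unname(ds0$degree), rep(0, 3))
  expect_equal(unname(ds0$strength), rep(0, 3))
})

test_that("distances use hop counts and inverse-weight lengths", {
  expect_equal(pairValues(distanceMatrix(pathGraph(3)))[1, 3], 2)
  chain <- pathGraph(3, w = 4)
  expect_equal(pairValues(distanceMatrix(chain, weighted = TRUE))[1, 3], 0.5)
  ## disconnected pairs carry the Inf sentinel
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  D <- pairValues(distanceMatrix(Connectome(W)))
  expect_identical(D[1, 3], Inf)
  expect_equal(diag(D), rep(0, 4))
})

test_that("betweenness matches hand values and the exhaustive oracle", {
  expect_equal(unname(betweennessCentrality(pathGraph(3))), c(0, 1, 0))
  expect_equal(unname(betweennessCentrality(completeGraph(3))), rep(0, 3))
  expect_equal(unname(betweennessCentrality(starGraph(4))[1]), 6)  # C(4,2)

  set.seed(71)
  for (i in 1:8) {
    n <- sample(4:7, 1)
    weighted <- i %% 2 == 0
    W <- randomW(n, runif(1, 0.4, 0.8), weighted = weighted)
    got <- betweennessCentrality(Connectome(W), weighted = weighted)
    expect_equal(unname(got), bruteBetweenness(W, weighted), tolerance = 1e-9)
  }
})

test_that("global efficiency follows the inverse-distance mean", {
  expect_equal(globalEfficiency(completeGraph(5)), 1)
  expect_equal(globalEfficiency(pathGraph(3)), 5 / 6)
  expect_equal(globalEfficiency(Connectome(matrix(0, 4, 4))), 0)
  expect_error(globalEfficiency(Connectome(matrix(0, 1, 1))), "2 nodes")
  ## removing an edge never increases efficiency
  set.seed(81)
  W <- randomConnectedW(9, 0.4)
  con <- Connectome(W)
  e0 <- globalEfficiency(con)
  el <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  for (k in seq_len(min(5, nrow(el)))) {
    W2 <- W; W2[el[k, 1], el[k, 2]] <- 0; W2[el[k, 2], el[k, 1]] <- 0
    expect_lte(globalEfficiency(Connectome(W2)), e0 + 1e-12)
  }
})

test_that("characteristic path length averages finite distances", {
  got <- characteristicPathLength(pathGraph(3))
  expect_equal(got$cpl, 4 / 3)
  expect_equal(got$disconnectedFraction, 0)
  expect_equal(characteristicPathLength(completeGraph(6))$cpl, 1)
  ## disconnected pair is excluded but reported
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  got2 <- characteristicPathLength(Connectome(W))
  expect_equal(got2$cpl, 1)
  expect_equal(got2$disconnectedFraction, 2 / 3)
  expect_error(characteristicPathLength(Connectome(matrix(0, 2, 2))),
               "no finite")
})

test_that("hub identification uses mean + 1 sample sd of degree", {
  ## degrees (5,1,1,1): star with 5 leaves plus 1 isolated... build directly
  W <- matrix(0, 6, 6)
  W[1, 2:6] <- W[2:6, 1] <- 1          # degrees 5,1,1,1,1,1
  con <- Connectome(W)
  deg <- degreeStrength(con)$degree
  thr <- mean(deg) + sd(deg)
  expect_identical(identifyHubs(con), unname(which(deg >= thr)))
  expect_identical(identifyHubs(con), 1L)

  ## regular graph: sd = 0 so every node satisfies the >= rule
  expect_identical(identifyHubs(completeGraph(4)), 1:4)

  ## degrees (3,3,2,2): threshold ~3.08 exceeds 3, no hubs
  W4 <- matrix(1, 4, 4) - diag(4)
  W4[3, 4] <- W4[4, 3] <- 0
  expect_length(identifyHubs(Connectome(W4)), 0)

  ## hemisphere filter applies after whole-network thresholding
  hemi_con <- Connectome(W, hemisphere = c("R", "L", "L", "L", "L", "L"))
  expect_identical(identifyHubs(hemi_con, hemisphere = "L"), integer(0))
  expect_identical(identifyHubs(hemi_con, hemisphere = "R"), 1L)
})

test_that("assortativity reordering sorts by degree and summarizes blocks", {
  ## star: the center (top block) communicates more with leaves than
  ## leaves do among themselves
  st <- starGraph(5)
  res <- communicabilityAssortativity(st, k = 1)
  expect_equal(res$order[length(res$order)], 1)  # center has max degree
  expect_gt(res$blockMeans[["cross"]], res$blockMeans[["bottom"]])

  ## already-sorted nodes give the identity permutation
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1; W[3, 4] <- W[4, 3] <- 1
  W[2, 4] <- W[4, 2] <- 1                      # degrees 1,3,2,... not sorted
  con <- Connectome(adjacency(Connectome(W)))
  ord <- communicabilityAssortativity(con)$order
  expect_identical(sort(ord), 1:4)

  ## empty graph: all block means zero
  res0 <- communicabilityAssortativity(Connectome(matrix(0, 6, 6)), k = 2)
  expect_equal(unname(res0$blockMeans), c(0, 0, 0))
})

test_that("top-node density is the induced subgraph density", {
  tri <- completeGraph(3)
  expect_equal(topNodeDensity(tri, c(3, 2, 1), k = 3), 1.0)
  W <- matrix(0, 6, 6); W[1, 4] <- W[4, 1] <- 1  # top-3 nodes unconnected
  con <- Connectome(W)
  expect_equal(topNodeDensity(con, c(5, 4, 3, 1, 1, 1), k = 3), 0)
  ## 4 chosen nodes with 3 of 6 edges
  W2 <- matrix(0, 5, 5)
  W2[1, 2] <- W2[2, 1] <- 1; W2[2, 3] <- W2[3, 2] <- 1; W2[3, 4] <- W2[4, 3] <- 1
  expect_equal(topNodeDensity(Connectome(W2), c(4, 3, 2, 1, 0), k = 4), 0.5)
  expect_error(topNodeDensity(tri, c(1, 2, 3), k = 1), "k must")
})

test_that("nodeMetricTable assembles all metrics with metadata", {
  con <- Connectome(randomConnectedW(8, 0.5, weighted = TRUE),
                    labels = sprintf("n%d", 1:8))
  tab <- nodeMetricTable(con)
  expect_identical(names(tab)[1:3], c("index", "label", "hemisphere"))
  expect_true(all(c("Deg", "Sw", "BC", "BCw", "Cm", "Cmw", "CBC", "CBCw")
                  %in% names(tab)))
  expect_equal(tab$Deg, unname(degreeStrength(con)$degree))
  hm <- hemisphericMeans(con, tab$Sw)
  expect_equal(hm[["L"]], mean(tab$Sw[hemispheres(con) == "L"]))
})
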