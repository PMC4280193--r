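test_that("Connectome construction enforces the matrix invariants", {
  expect_equal(nNodes(Connectome(matrix(0, 3, 3))), 3)

  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 2
  con <- Connectome(W)
  expect_equal(weightMatrix(con)[1, 2], 2)
  expect_equal(sum(adjacency(con)), 2)

  ## asymmetry above tolerance is an error, below is averaged away
  Wb <- matrix(0, 3, 3); Wb[1, 2] <- 2; Wb[2, 1] <- 3
  expect_error(Connectome(Wb), "asymmetric")
  Wc <- matrix(0, 3, 3); Wc[1, 2] <- 2; Wc[2, 1] <- 2 + 1e-12
  expect_equal(weightMatrix(Connectome(Wc))[1, 2], 2 + 5e-13)

  expect_error(Connectome(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
  Wd <- diag(2); expect_equal(diag(weightMatrix(Connectome(Wd * 0))), c(0, 0))
})

test_that("connectome save/load round-trips weights and metadata", {
  set.seed(42)
  W <- randomW(7, 0.5, weighted = TRUE)
  con <- Connectome(W, labels = sprintf("r%d", 1:7),
                    hemisphere = c(rep("L", 3), rep("R", 3), "other"),
                    coords = matrix(rnorm(21), 7, 3),
                    nodeSize = runif(7, 10, 100))
  mp <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  saveConnectome(con, mp, np)
  back <- loadConnectome(mp, np)
  expect_equal(weightMatrix(back), weightMatrix(con), tolerance = 1e-15)
  expect_identical(nodeLabels(back), nodeLabels(con))
  expect_identical(hemispheres(back), hemispheres(con))
  expect_equal(nodeCoords(back), nodeCoords(con), ignore_attr = TRUE)
  expect_equal(nodeSizes(back), nodeSizes(con))

  ## without coords/sizes the node table omits those columns
  bare <- Connectome(W)
  saveConnectome(bare, mp, np)
  cols <- names(read.delim(np))
  expect_false(any(c("x", "size") %in% cols))
  expect_equal(weightMatrix(loadConnectome(mp, np)), W, tolerance = 1e-15)

  ## CSV dialect by extension; empty graph round-trips
  cp <- tempfile(fileext = ".csv")
  saveConnectome(Connectome(matrix(0, 4, 4)), cp, np)
  expect_equal(sum(weightMatrix(loadConnectome(cp, np))), 0)
})

test_that("loadConnectome rejects malformed input", {
  mp <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  writeLines(c("0\t1", "1\t0"), mp)
  writeLines(c("label\themisphere", "a\tL", "b\tR", "c\tR"), np)
  expect_error(loadConnectome(mp, np), "dimension mismatch")
  writeLines(c("0\tx", "x\t0"), mp)
  writeLines(c("label\themisphere", "a\tL", "b\tR"), np)
  expect_error(loadConnectome(mp, np))
})

test_that("node-size correction divides by the endpoint size sum", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 10
  con <- Connectome(W, nodeSize = c(3, 2, 5))
  corr <- applyNodeSizeCorrection(con)
  expect_equal(weightMatrix(corr)[1, 2], 2.0)

  ## equal sizes rescale uniformly: edge ranking is preserved
  set.seed(7)
  W2 <- randomW(6, 0.6, weighted = TRUE)
  con2 <- Connectome(W2, nodeSize = rep(4, 6))
  corr2 <- applyNodeSizeCorrection(con2)
  expect_equal(weightMatrix(corr2), W2 / 8)

  expect_error(applyNodeSizeCorrection(Connectome(W)), "missing")
  ## divisor hook
  prod_corr <- applyNodeSizeCorrection(con, divisor = function(a, b) a * b)
  expect_equal(weightMatrix(prod_corr)[1, 2], 10 / 6)
})

test_that("average network applies the consensus presence rule", {
  ## edge (1,2) with weights 2, 4, 0, 6 across four subjects
  mk <- function(w) {
    W <- matrix(0, 3, 3)
    W[1, 2] <- W[2, 1] <- w
    W[2, 3] <- W[3, 2] <- 1     # shared edge keeps graphs comparable
    Connectome(W)
  }
  co <- Cohort(paste0("s", 1:4), lapply(c(2, 4, 0, 6), mk),
               lapply(c(2, 4, 0, 6), mk))
  avg75 <- buildAverageNetwork(co, presenceThreshold = 0.75, scanSelector = "a")
  expect_equal(weightMatrix(avg75)[1, 2], 4.0)  # mean over the 3 present
  avg80 <- buildAverageNetwork(co, presenceThreshold = 0.80, scanSelector = "a")
  expect_equal(weightMatrix(avg80)[1, 2], 0)
  ## all-subject mean variant shrinks by the presence fraction
  avgAll <- buildAverageNetwork(co, presenceThreshold = 0.75,
                                scanSelector = "a", weightMean = "all")
  expect_equal(weightMatrix(avgAll)[1, 2], 3.0)

  ## threshold 1 on identical copies returns the network exactly
  set.seed(11)
  W <- randomW(8, 0.4, weighted = TRUE)
  same <- Cohort(paste0("s", 1:3),
                 replicate(3, Connectome(W), simplify = FALSE),
                 replicate(3, Connectome(W), simplify = FALSE))
  expect_equal(weightMatrix(buildAverageNetwork(same, 1.0)), W)

  expect_error(buildAverageNetwork(Cohort(character(0), list(), list())),
               "empty")
})

test_that("average-network density is non-increasing in the threshold", {
  set.seed(3)
  subj <- replicate(6, Connectome(randomW(10, 0.4, weighted = TRUE)),
                    simplify = FALSE)
  co <- Cohort(paste0("s", 1:6), subj, subj)
  dens <- vapply(c(0.3, 0.5, 0.75, 0.9, 1.0), function(th) {
    sum(adjacency(buildAverageNetwork(co, th))) / 2
  }, numeric(1))
  expect_true(all(diff(dens) <= 0))
})

test_that("cohort manifest round-trips through JSON", {
  co <- tinyCohort(nSubjects = 3, n = 8, seed = 5)
  dir <- tempfile()
  writeCohort(co, dir)
  back <- readCohort(file.path(dir, "cohort.json"))
  expect_identical(subjectIds(back), subjectIds(co))
  expect_equal(weightMatrix(scanB(back, "s2")), weightMatrix(scanB(co, "s2")),
               tolerance = 1e-14)
  expect_identical(nodeLabels(scanA(back, 1)), nodeLabels(scanA(co, 1)))
})
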