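test_that("curve permutation test behaves at its boundaries", {
  ## identical constant sets: T = 0, every permutation ties, p = 1
  a <- matrix(0.5, 4, 6)
  res <- permutationTestCurves(a, a, nPerm = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  ## fully separated 4+4 sets: Monte-Carlo p approaches the exact
  ## enumeration fraction (2 of the 70 splits tie the observed |T|)
  hi <- matrix(1, 4, 5); lo <- matrix(0, 4, 5)
  exact <- exactPermFraction(hi, lo)
  expect_equal(exact, 2 / 70)
  res2 <- permutationTestCurves(hi, lo, nPerm = 4000, seed = 2)
  expect_lt(abs(res2$p - exact), 0.015)

  expect_error(permutationTestCurves(matrix(1, 2, 3), matrix(1, 2, 4)),
               "length mismatch")
})

test_that("permutation p matches exact enumeration on random curve sets", {
  set.seed(101)
  for (i in 1:4) {
    a <- matrix(rnorm(3 * 4), 3, 4)
    b <- matrix(rnorm(4 * 4, mean = i / 4), 4, 4)
    exact <- exactPermFraction(a, b)
    mc <- permutationTestCurves(a, b, nPerm = 4000,
                                seed = deriveSeed(101, "perm", i))$p
    expect_lt(abs(mc - exact), 0.03)
  }
})

test_that("paired t-tests recover hand-computed statistics", {
  ## differences (1, 2, 3): t = 2 / (1/sqrt(3)), df = 2
  base <- matrix(c(2, 4, 6), 3, 1)
  les <- matrix(c(1, 2, 3), 3, 1)
  res <- pairedTTestPerNode(base, les)
  expect_equal(res$t, sqrt(12), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-12)
  expect_equal(res$p, 0.07417990022, tolerance = 1e-8)
  expect_equal(res$meanChange, 2)

  ## no change: t = 0, p = 1; constant non-zero change: flagged sentinel
  same <- matrix(as.numeric(1:8), 4, 2)
  r0 <- pairedTTestPerNode(same, same)
  expect_equal(r0$t, c(0, 0))
  expect_equal(r0$p, c(1, 1))
  expect_true(all(r0$zeroVariance))
  shift <- same + 1
  r1 <- pairedTTestPerNode(shift, same)
  expect_equal(r1$p, c(0, 0))
  expect_true(all(r1$zeroVariance))
  ## direction check: near-constant positive differences give large |t|
  set.seed(5)
  jit <- same + 1 + matrix(rnorm(8, 0, 1e-4), 4, 2)
  r2 <- pairedTTestPerNode(jit, same)
  expect_true(all(r2$t > 100))
  expect_true(all(r2$p < 1e-4))

  expect_error(pairedTTestPerNode(matrix(1, 1, 2), matrix(1, 1, 2)),
               "2 subjects")
})

test_that("BH adjustment matches hand values and the brute-force oracle", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(111)
  for (i in 1:10) {
    p <- runif(sample(2:20, 1))
    expect_equal(fdrAdjust(p), bruteBH(p), tolerance = 1e-14)
  }
})

test_that("change reports mark FDR-significant nodes", {
  set.seed(121)
  base <- matrix(rnorm(60, 10), 6, 10)
  les <- base
  les[, 3] <- les[, 3] - 5           # one strongly changed node
  rep <- changeReport(base, les, alpha = 0.05)
  expect_true(rep$significant[3])
  expect_equal(sum(rep$significant), 1)
  expect_true(all(rep$pAdj >= rep$p - 1e-15))
})

test_that("sensitivity summary counts significant nodes per step", {
  mk <- function(sig) {
    data.frame(node = 1:4, significant = sig)
  }
  reports <- list(mk(rep(FALSE, 4)), mk(rep(FALSE, 4)),
                  mk(c(FALSE, FALSE, TRUE, FALSE)))
  s <- sensitivitySummary(reports)
  expect_equal(s$nSignificant, c(0, 0, 1))
  expect_equal(s$earliestStep, 3)
  ## no significance anywhere: Inf sentinel
  s0 <- sensitivitySummary(reports[1:2])
  expect_identical(s0$earliestStep, Inf)
  ## excluding the lesioned node removes its count
  s1 <- sensitivitySummary(reports, excludeNodes = 3)
  expect_identical(s1$earliestStep, Inf)
  expect_error(sensitivitySummary(list()), "no reports")
})

test_that("distance from lesion takes the minimum over sites and kinds", {
  p3 <- pathGraph(3)
  expect_equal(distanceFromLesion(p3, 1, "binary"), c(0, 1, 2))
  ## two sites: elementwise minimum of single-site vectors
  d1 <- distanceFromLesion(p3, 1, "binary")
  d3 <- distanceFromLesion(p3, 3, "binary")
  expect_equal(distanceFromLesion(p3, c(1, 3), "binary"), pmin(d1, d3))
  ## weighted distances use 1/w lengths
  ch <- pathGraph(3, w = 4)
  expect_equal(distanceFromLesion(ch, 1, "weighted"), c(0, 0.25, 0.5))
  ## euclidean needs coordinates; 3-4-5 triangle
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  con <- Connectome(W, coords = rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(distanceFromLesion(con, 1, "euclidean"), c(0, 5))
  expect_error(distanceFromLesion(p3, 1, "euclidean"), "coordinates")
})

test_that("change-distance correlations match textbook values", {
  d <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlateChangeDistance(10 - 2 * d, d, "pearson"), -1)
  ## monotone nonlinear: Spearman -1, |Pearson| < 1
  ch <- exp(-d)
  expect_equal(correlateChangeDistance(ch, d, "spearman"), -1)
  expect_gt(correlateChangeDistance(ch, d, "pearson"), -1)
  ## hand-computed Pearson to high precision
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlateChangeDistance(x, y, "pearson"), r_hand,
               tolerance = 1e-12)
  ## degenerate input returns the NA sentinel
  expect_true(is.na(correlateChangeDistance(rep(1, 5), d[1:5], "pearson")))
  expect_true(is.na(correlateChangeDistance(d[1:2], d[1:2], "pearson")))
  ## exclusion drops lesion sites and non-finite distances
  d2 <- c(Inf, 2, 3, 4, 5, 6)
  expect_equal(correlateChangeDistance(10 - 2 * d2, d2, "pearson",
                                       excludeNodes = 1), -1)
})

test_that("random-permutation null correlations concentrate near zero", {
  set.seed(131)
  n <- 400
  d <- runif(n)
  r <- correlateChangeDistance(sample(d), d, "pearson")
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("distance correlation table mirrors individual and average columns", {
  set.seed(141)
  ns <- 5; n <- 12
  dist <- matrix(rep(1:n, each = ns), ns, n) + matrix(runif(ns * n), ns, n)
  changes <- list(Sw = 5 - 0.3 * dist + matrix(rnorm(ns * n, 0, 0.1), ns, n))
  tab <- distanceCorrelationTable(changes,
                                  list(DistW = dist, DistB = round(dist)))
  expect_identical(tab$method[tab$distKind == "DistW"], "pearson")
  expect_identical(tab$method[tab$distKind == "DistB"], "spearman")
  expect_true(all(tab$individualMean < -0.9))
  expect_true(all(abs(tab$average) <= 1))
  ## average column correlates the across-subject means
  avg_r <- correlateChangeDistance(colMeans(changes$Sw), colMeans(dist),
                                   "pearson")
  expect_equal(tab$average[tab$distKind == "DistW"], avg_r)
})

test_that("change-location ranking counts top-k significant nodes", {
  mk <- function(sigNode) {
    data.frame(node = 1:5, label = paste0("n", 1:5),
               pAdj = ifelse(1:5 == sigNode, 0.01, 0.9),
               significant = 1:5 == sigNode)
  }
  reports <- c(replicate(9, mk(3), simplify = FALSE),
               replicate(16, mk(2), simplify = FALSE))
  tab <- reportChangeLocations(reports, k = 2)
  expect_equal(tab$fraction[tab$node == 3], 9 / 25)
  expect_equal(tab$fraction[tab$node == 2], 16 / 25)
  ## damaged nodes are excluded
  tab2 <- reportChangeLocations(reports, damagedNodes = 2, k = 2)
  expect_false(2 %in% tab2$node)
  ## nothing significant anywhere: empty table
  none <- replicate(3, {
    d <- mk(1); d$significant <- FALSE; d
  }, simplify = FALSE)
  expect_equal(nrow(reportChangeLocations(none)), 0)
})
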