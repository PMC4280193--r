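## Fixture builders and independent brute-force oracles. All fixtures are
## generated in code; the oracles deliberately avoid the package's own
## computational paths (no matrix exponential, no igraph shortest paths).

pathGraph <- function(n, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- w
  Connectome(W)
}

starGraph <- function(nLeaves, w = 1) {
  n <- nLeaves + 1
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- w
  Connectome(W)
}

completeGraph <- function(n, w = 1) {
  Connectome(w * (matrix(1, n, n) - diag(n)))
}

## Erdos-Renyi weight matrix; weights lognormal when weighted
randomW <- function(n, p, weighted = FALSE) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  edge <- stats::runif(sum(up)) < p
  w <- if (weighted) stats::rlnorm(sum(up)) else 1
  W[up] <- edge * w
  W + t(W)
}

## random connected graph (resamples until connected)
randomConnectedW <- function(n, p, weighted = FALSE) {
  repeat {
    W <- randomW(n, p, weighted)
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(W)
  }
}

## small two-scan cohort from perturbed copies of one base network
tinyCohort <- function(nSubjects = 4, n = 12, seed = 1, noiseSd = 0.05) {
  set.seed(seed)
  base <- randomConnectedW(n, 0.35, weighted = TRUE)
  hemi <- rep(c("L", "R"), each = n / 2)
  labels <- c("Left-Thalamus", "Left-Caudate",
              paste0("lh", seq_len(n / 2 - 2)),
              "Right-Thalamus", "Right-Caudate",
              paste0("rh", seq_len(n / 2 - 2)))
  coords <- cbind(ifelse(hemi == "L", -20, 20) + rnorm(n, 0, 4),
                  rnorm(n, 0, 10), rnorm(n, 0, 10))
  mk <- function() {
    noise <- matrix(rlnorm(n * n, -noiseSd^2 / 2, noiseSd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    Connectome(base * noise, labels = labels, hemisphere = hemi,
               coords = coords)
  }
  Cohort(sprintf("s%d", seq_len(nSubjects)),
         scanA = replicate(nSubjects, mk(), simplify = FALSE),
         scanB = replicate(nSubjects, mk(), simplify = FALSE))
}

## ---- oracles ----

## truncated-series matrix exponential: sum_{k=0}^{kmax} M^k / k!
seriesExpm <- function(M, kmax = 30) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(kmax)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

## exhaustive all-simple-paths betweenness (fractional credit over
## equally short paths); lengths are 1 (binary) or 1/w (weighted)
bruteBetweenness <- function(W, weighted = FALSE) {
  n <- nrow(W)
  len <- matrix(Inf, n, n)
  len[W > 0] <- if (weighted) 1 / W[W > 0] else 1
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      paths <- list()
      dfs <- function(path, total) {
        v <- path[length(path)]
        if (v == t) {
          paths[[length(paths) + 1]] <<- list(path = path, len = total)
          return()
        }
        for (u in which(W[v, ] > 0)) {
          if (!(u %in% path)) dfs(c(path, u), total + len[v, u])
        }
      }
      dfs(s, 0)
      if (length(paths) == 0) next
      ls <- vapply(paths, `[[`, numeric(1), "len")
      short <- paths[ls < min(ls) + 1e-12]
      for (p in short) {
        inner <- setdiff(p$path, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(short)
      }
    }
  }
  bc
}

## Benjamini-Hochberg by explicit sort and right-to-left cumulative min
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in seq.int(n - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## exact permutation-test null: fraction of all label splits whose |T|
## reaches |T| of the observed split (first na rows as group A)
exactPermFraction <- function(curvesA, curvesB) {
  pooled <- rbind(curvesA, curvesB)
  na <- nrow(curvesA)
  stat <- function(idx) {
    sum(colMeans(pooled[idx, , drop = FALSE]) -
          colMeans(pooled[-idx, , drop = FALSE]))
  }
  tObs <- abs(stat(seq_len(na)))
  splits <- utils::combn(nrow(pooled), na)
  hits <- sum(apply(splits, 2, function(idx) abs(stat(idx)) >= tObs - 1e-12))
  hits / ncol(splits)
}
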