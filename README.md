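# commlesion

Communicability metrics and simulated lesion analysis for structural
brain networks.

## What this package is for

Structural connectomes — weighted, undirected networks whose nodes are
gray-matter parcels and whose edge weights quantify white-matter
connection strength — are usually summarized with shortest-path metrics
(degree, strength, betweenness, path length, global efficiency). Those
metrics assume information flows only along shortest paths.
*Communicability* drops that assumption: it counts walks of **every**
length between two nodes, down-weighting longer walks by the factorial
of their length, which makes it a natural probe of the parallel and
indirect pathways thought to support integration and post-lesion
reorganization in the brain.

`commlesion` is for researchers who want to (a) compute communicability
metrics next to the standard ones, (b) stress-test them with simulated
lesions — targeted node attacks, small perturbations of nodes and
edges, a simulated subcortical stroke — under realistic two-scan
measurement noise, and (c) quantify metric sensitivity with the
accompanying statistics (permutation tests on efficiency decay curves,
per-node paired t-tests with FDR correction, change-versus-distance
correlations).

## The metrics at the core

For a binary adjacency matrix `A` (entry 1 when an edge is present),
the communicability between nodes i and j is

    Cm[i,j] = sum_k (A^k)[i,j] / k!  =  exp(A)[i,j]

since `(A^k)[i,j]` counts walks of length k. The weighted form first
normalizes by node strength `s_i = sum_j W[i,j]`:

    Cm^w = exp( S^(-1/2) W S^(-1/2) ),   S = diag(s_i)

which damps the otherwise dominant contribution of high-strength nodes
and makes the result invariant to global weight rescaling.

*Communicability centrality* (CBC) of a node r measures how much the
communicability among all **other** pairs drops when r is removed:

    CBC(r) = (1/K) * sum_{i!=j, i,j!=r} (Cm[i,j] - Cm_r[i,j]) / Cm[i,j]

where `Cm_r` is recomputed with r's row and column zeroed and K counts
the terms (ordered pairs with `Cm[i,j] > 0`). Because removing a node
can only remove walks, every term — and hence CBC — lies in [0, 1]: an
isolated node scores 0, the center of a star scores 1.

Alongside these, the package computes degree, strength, weighted and
binary betweenness and shortest-path distances (weighted length of an
edge is `1/w`), characteristic path length and global efficiency, hub
identification (degree at least one SD above the mean), communicability
assortativity matrices, and top-node subgraph density.

## Worked example

```r
library(commlesion)

## a synthetic two-scan cohort: 6 subjects, 30 bihemispheric nodes,
## heavy-tailed weights, designated subcortical hubs
co  <- generateCohort(cohortSpec(nSubjects = 6, nNodes = 30, seed = 11))
avg <- buildAverageNetwork(co, presenceThreshold = 0.75)
avg
#> Connectome: 30 nodes, 93 edges (density 0.214)
#>   hemispheres: L=15 R=15 other=0
#>   coords: yes; node sizes: no

tab <- nodeMetricTable(avg, metrics = c("Deg", "Sw", "Cm", "CBC"))
head(tab[order(-tab$CBC), ], 4)
#>    index          label hemisphere Deg       Sw       Cm       CBC
#> 16    16 Right-Thalamus          R  13 13.91580 2694.716 0.4960967
#> 17    17  Right-Caudate          R  12 15.53858 2559.740 0.4649818
#> 1      1  Left-Thalamus          L  12 14.21677 2083.092 0.4253125
#> 15    15   ctx-lh-roi13          L   8 22.49102 1622.523 0.2506920

globalEfficiency(avg)
#> [1] 0.5609
nodeLabels(avg)[identifyHubs(avg)]
#> [1] "Left-Thalamus"  "Right-Thalamus" "Right-Caudate"
```

The highest-CBC nodes are the planted subcortical hubs: removing any of
them would erase about half of the network's pairwise communicability.
A targeted attack guided by CBC (criterion recomputed after each
removal) then shows the efficiency cost of losing them:

```r
tr <- targetedAttack(avg, criterion = "CBC", method = "single_choice",
                     nAttacks = 5)
round(tr@effBinary, 4)
#> [1] 0.5609 0.5448 0.5224 0.4996 0.4895 0.4738
```

Longitudinal lesion experiments and their statistics run through
`runSmallPerturbations()`, `runTargetedAttacks()` and
`runStrokePreset()`; see the methods vignette
(`vignettes/communicability-lesions.Rmd`) for the full model
description, parameter meanings and design choices.

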