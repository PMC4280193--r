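---
title: "Communicability metrics and simulated lesions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communicability metrics and simulated lesions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `commlesion`, the
parameters that matter, the numerical and design choices made where the
definitions left room, and what the synthetic validation does and does
not demonstrate about real data.

# Data model

A `Connectome` is a weighted, undirected, loop-free network over a fixed
parcellation: a symmetric non-negative weight matrix `W` with zero
diagonal, plus per-node metadata (label, hemisphere tag, optional 3-D
coordinates in mm and region size in voxels). The binary adjacency `A`
is derived as `A[i,j] = 1` iff `W[i,j] > 0`. A `Cohort` holds two scans
per subject over a shared node order; which scan plays the baseline role
is decided at analysis time by a seeded per-subject coin flip, mirroring
a longitudinal design in which the two acquisitions are interchangeable
measurements of the same anatomy.

File input is deliberately plain: dense TSV/CSV matrices, a TSV node
table, and a JSON cohort manifest. Asymmetries up to a relative `1e-8`
are averaged away (they arise from round-tripping through text); larger
asymmetries fail loudly rather than being silently symmetrized, since
they usually indicate a malformed file rather than numeric noise.

Connectivity indices from probabilistic tractography scale with seed and
target region size, so `applyNodeSizeCorrection()` divides each weight
by a symmetric function of the endpoint sizes. The default divisor is
`size_i + size_j`: it is symmetric, monotone in the raw weight, and
penalizes large parcels without changing the sign or order of edges
within a row. The divisor is an argument, because no single correction
is canonical; the product and the geometric mean are the common
alternatives and can be swapped in.

The group-average network uses the consensus rule: an edge enters when
present in at least `presenceThreshold` (default 75%) of the selected
scans. Its weight defaults to the mean over the subjects *in which the
edge is present*; averaging over all subjects (absent-as-zero) is
offered as an option but shrinks consensus edges by the presence
fraction, coupling weights to the threshold, which is rarely wanted.

# Communicability

Binary communicability is the matrix exponential of the adjacency,
`Cm = exp(A)`: entry (i, j) sums all walks between i and j weighted by
`1/k!` in the walk length k. The weighted form first normalizes by node
strength, `Cm^w = exp(S^{-1/2} W S^{-1/2})` with `S = diag(s_i)`,
`s_i = Σ_j W[i,j]`; this regulates the influence of high-strength nodes
and makes `Cm^w` invariant to multiplying `W` by any positive constant
(a property the test suite checks explicitly, since connectivity indices
have arbitrary global scale). Isolated nodes get `1/sqrt(s_i) := 0`, so
they stay isolated instead of producing divisions by zero — lesion
simulations routinely create isolated nodes mid-run.

Because all matrices involved are symmetric, the exponential is computed
by spectral decomposition (`V diag(e^λ) V'`), which is exact up to
floating point, preserves symmetry, and handles the negative eigenvalues
of adjacency matrices without series truncation. Two numerical
guards are applied afterwards: entries between different connected
components are set to exactly zero (their true communicability is zero;
the eigensolver leaves ~1e-16 residue), and tiny negative residues are
clamped to zero. An independent truncated-series oracle
(`Σ_{k≤30} M^k/k!`) confirms agreement to 1e-9 on small graphs.

## Communicability centrality

CBC measures the drop in communicability among the *remaining* pairs
when one node is removed:

CBC(r) = (1/K) Σ (Cm[i,j] − Cm⁽ʳ⁾[i,j]) / Cm[i,j]

over ordered pairs i ≠ j with i, j ≠ r and `Cm[i,j] > 0`, where K is the
number of such pairs. Pairs with zero communicability are excluded from
both the sum and K (they can lose nothing). Removing node r is
implemented by zeroing its row and column, which is walk-equivalent to
deleting the node for every retained pair while keeping the matrix size
fixed.

Two genuinely open points were settled as follows:

* **Relative vs absolute reduction.** The relative (ratio) form is the
  default because it is the only reading under which the stated bound
  CBC ∈ [0, 1] holds: removing a node can only remove walks, so each
  ratio lies in [0, 1] term by term. The absolute-reduction variant
  (`relative = FALSE`) is available for sensitivity checks; it is
  non-negative but not bounded by 1.
* **Weighted CBC normalization.** When the lesioned network is
  re-normalized by its *own* strengths, the bound fails: on a
  unit-weight triangle, removing one node raises the remaining pair's
  normalized communicability from `(e − e^{−1/2})/3 ≈ 0.704` to
  `sinh(1) ≈ 1.175`, a ratio of −0.67 — lowering strengths inflates the
  surviving normalized weights. The default therefore keeps the intact
  network's strength normalization when exponentiating the lesioned
  matrix, which preserves entrywise monotonicity and hence the [0, 1]
  bound; `renormalize = TRUE` exposes the other reading.

Each per-term ratio is clamped into [0, 1] as a numerical guard: the
bound holds in exact arithmetic, and the clamp only removes ±1e-16
eigensolver residue (relevant, e.g., when a node's removal barely
changes the spectrum).

# Standard metrics

Shortest-path machinery is delegated to igraph. Weighted path lengths
use `1/w` — the standard convention when weights are connectivity
indices, where a heavier edge is a shorter, easier link. Betweenness is
unnormalized with fractional credit over equally short paths (checked
against an exhaustive path-enumeration oracle on graphs with up to 7
nodes). Global efficiency is the mean inverse distance over ordered
pairs with `1/∞ = 0`, so it degrades smoothly under disconnection; for
that reason it is the primary global summary in the lesion analyses,
while characteristic path length is reported as the mean over *finite*
pairs together with the disconnected fraction (and errors when no finite
pair exists). Hubs are nodes with degree at least one sample standard
deviation (n−1 denominator) above the mean; at `sd = 0` (regular graph)
the ≥ rule makes every node a hub, which is the boundary reading that
keeps the rule total. Ties in every top-k or max-criterion selection are
broken by lowest node index, making all rankings deterministic.

# Lesion simulation

Targeted attacks remove nodes one at a time by maximal criterion value,
either recomputing the criterion after every removal (*single-choice*)
or freezing the ranking on the intact network (*hubs order*). Node
removal deletes the row and column (the network shrinks); binary and
weighted global efficiency are recorded after every removal, with the
intact value at index 1. If the criterion or efficiency becomes
undefined mid-run the trace is truncated and flagged rather than padded
silently.

Small perturbations keep the node count fixed: binary node lesions
delete exactly `round(R · Deg)` of a node's connections (half away from
zero, floored at one edge — plain `round()` in R rounds half to even,
which would make R = 0.5 on odd degrees irreproducible across
platforms); weighted node lesions multiply all incident weights by
`1 − R`, leaving the topology (and hence every binary metric) untouched
for R < 1; edge lesions remove single edges uniformly at random, with
the ordered removal list logged so any intermediate network can be
reconstructed.

The longitudinal driver assigns baseline/lesion roles by a seeded coin
flip per subject, applies lesions cumulatively, and repeats the whole
procedure with fresh target draws per repetition. Shared target lists
come from the cohort's average network (per-subject hub sets differ, so
a shared list needs a group-level reference); the default target count
for hub lesions is the floor of the median per-scan hub count in the
chosen hemisphere. For shared *edge* lesions, the edge sequence is drawn
from the average network so the same anatomical connections are removed
in every subject; removals of an edge a subject lacks are no-ops.

All randomness is derived from one root seed through labelled streams
(`deriveSeed(seed, "rep", r, "targets", id, ...)`), so per-subject and
per-repetition draws are independent yet fully reproducible, and any
report bundle can be regenerated bit-identically from its embedded
config — which the acceptance suite verifies.

The stroke preset lesions the left thalamus and left caudate (labels
configurable), with a per-subject lesion rate drawn uniformly from
[0.2, 0.8] — the same rate range used by the node lesions, since only
"random" is specified — in both weighted and binary form, averaged over
10 repetitions, and reports global, hemispheric (ipsi-/contralesional)
and per-node comparisons.

# Statistics

Efficiency decay curves for two strategies are compared by a label
permutation test with statistic `T = Σ_steps (mean_A − mean_B)`; the
two-sided p-value uses the `(+1)/(+1)` convention (the observed labeling
counts as one permutation), so p is never exactly 0. Sidedness is not
dictated by the procedure's description, and two-sided via |T| is the
conservative default. The default 5000 permutations match the analysis
the package reproduces.

Per-node changes use classical paired t-tests on subject-wise
differences, with Benjamini–Hochberg FDR correction across nodes; the
family is one metric at one lesion step (the natural unit in which
results are read), and α = 0.05 after correction. Two degenerate cases
arise in practice and are handled explicitly: all differences exactly
zero (binary metrics under weighted lesions) gives t = 0, p = 1; and
identical non-zero differences gives a flagged p = 0 sentinel rather
than NaN. Repetitions are tested separately and summarized afterwards
(test-then-average), matching how averaged significant-change counts are
reported; pooling before testing is possible by passing concatenated
matrices.

Change-versus-distance tables report, per metric and distance kind, the
per-subject correlation (mean ± sd) and the correlation of the
across-subject mean change with the mean distance. Weighted and
Euclidean distances use Pearson; the binary hop distance is ordinal, so
Spearman is the default there. Lesion sites and non-finite distances are
always excluded, and constant inputs return an NA sentinel rather than
propagating NaN.

# The synthetic cohort generator

The generator provides the study conditions for end-to-end validation:
19 subjects and an 86-node bihemispheric parcellation by default, nodes
on two lateralized coordinate clusters, and a group-level backbone drawn
with distance-decaying connection probabilities scaled to a target
density of 0.20 — so the 75% consensus rule behaves as it does in real
cohorts, where subjects share most of their edges. About 12% of nodes
per hemisphere (always including the named subcortical nodes, so the
stroke preset runs unmodified) are designated hubs with a 3× connection
probability multiplier, which the degree rule recovers reliably. Edge
weights are log-normal (meanlog 0, sdlog 1): positive, right-skewed and
heavy-tailed, like connectivity indices.

The second scan models test-retest measurement noise, and only
measurement noise:

* every weight is multiplied by mean-one log-normal noise
  (`exp(N(−σ²/2, σ))`, σ = 0.1 — about 10% weight variability, typical
  of test-retest tractography);
* presence flicker: with probability 0.01 an edge slot *redraws* its
  presence from the same inclusion law as the first scan, and only weak
  slots (bottom quartile of backbone weights, or spurious edges) are
  eligible. Both restrictions are deliberate: near-detection-threshold
  connections are the ones that flicker between sessions, strong tracts
  do not vanish; and redrawing from the same law makes the two scans
  exchangeable — identical marginals, no systematic edge loss — so
  baseline group comparisons are null by construction, which is the
  property the two-scan design requires. An earlier draft that flipped
  presence uniformly violated this in practice: rare whole-weight jumps
  on strong edges made the far tail of the per-node t statistics
  unreliable and produced spurious baseline findings.

`injectDistanceDecayingEffect()` adds a controlled ground truth for
recovery tests: node i's incident weights in scan B are scaled by
`1 − amplitude · exp(−decayRate · d_i)` with `d_i` the binary distance
from the focus, each edge receiving both endpoint factors. With
amplitude 1 the focus nodes are disconnected outright, which is required
for any *binary* metric (CBC, Deg) to respond at all — smaller
amplitudes change weights but not topology. Because the ground truth is
multiplicative, the induced monotone change-vs-distance relationship
lives on the *relative*-change scale for strength (whose baseline values
are log-normally heterogeneous across nodes); recovery tests for
strength therefore correlate relative changes with distance, while CBC —
already normalized to [0, 1] — is tested on raw changes.

## What the generator does and does not emulate

It reproduces the features the analyses rely on: bihemispheric layout
with named subcortical hubs, consensus-stable backbone, heavy-tailed
positive weights, hub degree structure, and exchangeable two-scan
measurement noise. It does **not** emulate spatially structured
tractography error, distance-dependent weight biases, atlas-specific
topology, rich-club organization beyond what the hub multiplier
induces, or any reorganization after damage. Passing validation on this
generator therefore shows that the pipeline recovers known effects
under realistic noise — not that effect sizes on real connectomes will
match, and not that the lesion model captures post-injury plasticity
(it deliberately contains none).

# Validation scales

The test suite exercises: closed-form communicability values (single
edge, triangle, normalized triangle, star and path CBC boundaries) to
1e-9; truncated-series, exhaustive-betweenness, brute-force-BH and
exact-permutation oracles on small instances; CBC bounds on an ensemble
of 200 random connected graphs with 10–60 nodes and edge probabilities
0.1–0.5; baseline equivalence over 100 seeded default cohorts (zero
FDR-significant strength differences in at least 95% of seeds, the
bound an exactly calibrated null attains); the single-choice vs
hubs-order efficiency ordering over 20 cohorts of 15 subjects × 60
nodes with 15 attacks; ground-truth recovery over 50 cohorts of 19
subjects × 60 nodes with a five-hub right-hemisphere focus (mirroring
the five-hub-lesion situation in which change-distance correlations are
classically read); and bit-identical reproduction of report bundles
from their embedded configs. The 60-node networks in the simulation
checks keep the n-fold eigendecompositions of CBC cheap while staying
inside the 86–154-node regime the package targets.

# Known limitations

* CBC costs one eigendecomposition per node (O(n⁴) overall); fine for
  86–154-node parcellations, slow beyond ~500 nodes.
* The permutation test assumes exchangeable curves across the pooled
  set; subjects contributing curves to both strategy sets violate
  independence between groups (as in the paired design it is applied
  to), making it a randomization test of curve-set equality rather than
  a strict two-sample test.
* The paired t-test's validity at 19 subjects relies on approximate
  normality of per-node differences; the zero-variance sentinels flag
  the degenerate cases but heavy-tailed difference distributions will
  still distort far-tail p-values.
* Weighted-distance and betweenness results depend on the `1/w` length
  convention; other monotone mappings change numbers but not orderings
  of the lesion analyses validated here.
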