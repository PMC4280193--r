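Package: commlesion
Title: Communicability Metrics and Simulated Lesion Analysis for Structural
    Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes matrix-exponential communicability, normalized weighted
    communicability and communicability centrality for weighted undirected
    structural connectomes, alongside standard graph metrics (degree, strength,
    betweenness, shortest-path distances, characteristic path length, global
    efficiency). Simulates targeted attacks and small node/edge perturbations
    on two-scan longitudinal cohorts, including a subcortical stroke preset,
    and quantifies metric sensitivity with permutation tests on efficiency
    decay curves, per-node paired t-tests with false discovery rate
    correction, and change-versus-distance-from-lesion correlation tables.
    Ships a synthetic two-scan cohort generator with controlled effect
    injection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'commlesion-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'connectome.R'
    'io.R'
    'average-network.R'
    'communicability.R'
    'metrics.R'
    'lesion.R'
    'longitudinal.R'
    'stats.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
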