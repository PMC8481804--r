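Package: scnet
Title: Structural Covariance Network Analysis of Regional Cortical Thickness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs and compares group-level structural covariance
    networks (SCNs) from region-averaged cortical thickness. Builds
    age-adjusted inter-regional Pearson association matrices per group,
    thresholds them into binary graphs across a density sweep, computes
    global and nodal graph-theory measures (clustering, path length,
    efficiency, transitivity, modularity, small-world indices against
    degree-preserving rewired nulls, degree, betweenness), performs
    non-parametric permutation inference on between-group differences per
    density and by area under the curve with false-discovery-rate control,
    and identifies network hubs by a betweenness z-threshold. Ships
    Desikan-Killiany (68 region) and Destrieux (148 region) atlas
    definitions, readers for FreeSurfer-style thickness tables, and a
    synthetic two-group cohort generator with controllable covariance
    communities, age confounds, group contrasts and planted hubs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'atlas.R'
    'io.R'
    'covariance.R'
    'metrics.R'
    'hubs.R'
    'inference.R'
    'synthetic.R'
    'pipeline.R'
    'scnet-package.R'
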