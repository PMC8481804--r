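#' @include AllClasses.R
NULL

#' @describeIn BrainAtlas number of regions in an atlas.
#' @param x a `BrainAtlas` (or object carrying one).
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @describeIn BrainAtlas region column names in atlas order
#'   (`lh_<label>` / `rh_<label>`, the `aparcstats2table` convention).
#' @export
setGeneric("regionColumns", function(x) standardGeneric("regionColumns"))

#' @describeIn BrainAtlas per-region hemisphere tags (`"left"`/`"right"`).
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' Extract the atlas bound to an object
#' @param x a [ThicknessExperiment] or [CohortConfig].
#' @return a [BrainAtlas].
#' @export
setGeneric("atlas", function(x) standardGeneric("atlas"))

#' Subject-by-region thickness values
#'
#' Returns the thickness assay transposed to the user-facing orientation:
#' one row per subject, one column per atlas region (mm).
#'
#' @param x a [ThicknessExperiment].
#' @return numeric matrix, subjects x regions.
#' @export
setGeneric("thicknessValues", function(x) standardGeneric("thicknessValues"))

#' Per-subject group labels
#' @param x a [ThicknessExperiment].
#' @return character vector.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Per-subject ages in years
#' @param x a [ThicknessExperiment].
#' @return numeric vector.
#' @export
setGeneric("subjectAges", function(x) standardGeneric("subjectAges"))

#' Remove the linear age effect from every region column
#'
#' Replaces each region's thickness by the residuals of an ordinary
#' least-squares fit on intercept + age, computed across the subjects of the
#' supplied table. Residual columns have zero mean and zero correlation with
#' age. With a constant age column the fit is degenerate; the table is
#' mean-centred instead and a warning is raised.
#'
#' @param x a [ThicknessExperiment] with at least 3 subjects.
#' @return a [ThicknessExperiment] whose assay holds residuals
#'   (`metadata(x)$residualized` is set to `TRUE`).
#' @export
setGeneric("residualizeAge", function(x) standardGeneric("residualizeAge"))

#' Inter-regional Pearson association matrix of one group
#'
#' Correlates age-adjusted thickness between every pair of regions across
#' the subjects of a single group, forcing the diagonal to zero. Supply a
#' table already passed through [residualizeAge()] to control the adjustment
#' yourself; otherwise age is residualized internally first.
#'
#' @param x a [ThicknessExperiment] holding one group, >= 4 subjects.
#' @param ... passed to methods.
#' @return an [AssociationMatrix].
#' @export
setGeneric("associationMatrix",
           function(x, ...) standardGeneric("associationMatrix"))

#' Correlation values of an association matrix
#' @param x an [AssociationMatrix].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("assocValues", function(x) standardGeneric("assocValues"))

#' Adjacency matrix of a binary network
#' @param x a [BinaryNetwork].
#' @return symmetric integer 0/1 matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Density of a binary network
#' @param x a [BinaryNetwork].
#' @return edge count divided by `n(n-1)/2`.
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' Number of edges in a binary network
#' @param x a [BinaryNetwork].
#' @return integer edge count.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Convert a binary network to an igraph graph
#' @param x a [BinaryNetwork].
#' @return an undirected [igraph][igraph::igraph-package] graph with region
#'   names as vertex names.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Hub regions of a hub report
#' @param x a [HubReport].
#' @return character vector of hub regions, betweenness-descending.
#' @export
setGeneric("hubRegions", function(x) standardGeneric("hubRegions"))
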