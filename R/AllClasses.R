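#' @include utils.R
NULL

#' Atlas definition for region-averaged cortical measures
#'
#' A `BrainAtlas` names an ordered set of cortical regions, each tagged with
#' a hemisphere. Region order is authoritative: thickness tables, association
#' matrices and networks all follow it. Use [builtinAtlas()] for the bundled
#' Desikan-Killiany (68 regions) and Destrieux (148 regions) definitions.
#'
#' @slot name single character identifier of the atlas.
#' @slot regions `data.frame` with columns `label` (unique within hemisphere)
#'   and `hemisphere` (`"left"` or `"right"`).
#'
#' @seealso [builtinAtlas()], [regionColumns()]
#' @exportClass BrainAtlas
setClass("BrainAtlas",
  slots = c(name = "character", regions = "data.frame"))

setValidity("BrainAtlas", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  reg <- object@regions
  if (!all(c("label", "hemisphere") %in% colnames(reg))) {
    msg <- c(msg, "'regions' needs columns 'label' and 'hemisphere'")
  } else {
    if (!all(reg$hemisphere %in% c("left", "right")))
      msg <- c(msg, "hemisphere tags must be 'left' or 'right'")
    key <- paste(reg$hemisphere, reg$label)
    if (anyDuplicated(key))
      msg <- c(msg, "region (hemisphere, label) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Subject-by-region cortical thickness container
#'
#' `ThicknessExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a `"thickness"` assay (regions in rows, subjects in columns, values in
#' millimetres), per-subject `group` and `age` in `colData`, and the
#' [BrainAtlas] the rows are bound to. Row order always equals atlas order.
#'
#' Thickness must be strictly positive and complete; after
#' [residualizeAge()] the assay holds signed residuals and the object carries
#' `metadata(x)$residualized = TRUE`, which relaxes the positivity check.
#'
#' @slot atlas the [BrainAtlas] defining row identity and order.
#'
#' @seealso [ThicknessExperiment()], [readThicknessTable()], [generateCohort()]
#' @exportClass ThicknessExperiment
setClass("ThicknessExperiment",
  contains = "SummarizedExperiment",
  slots = c(atlas = "BrainAtlas"))

setValidity("ThicknessExperiment", function(object) {
  msg <- character()
  if (!"thickness" %in% SummarizedExperiment::assayNames(object))
    return("assay 'thickness' is required")
  x <- SummarizedExperiment::assay(object, "thickness")
  expected <- regionColumns(object@atlas)
  if (!identical(rownames(object), expected))
    msg <- c(msg, "row names must equal the atlas region columns, in order")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "age") %in% colnames(cd)))
    return(c(msg, "colData needs 'group' and 'age'"))
  if (anyNA(x))
    msg <- c(msg, "thickness must have no missing cells")
  resid <- isTRUE(S4Vectors::metadata(object)$residualized)
  if (!resid && !anyNA(x) && any(x <= 0))
    msg <- c(msg, "thickness values must be strictly positive")
  if (anyNA(cd$group) || anyNA(cd$age))
    msg <- c(msg, "every subject needs a group label and an age")
  if (is.numeric(cd$age) && !anyNA(cd$age) && any(cd$age < 0))
    msg <- c(msg, "ages must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Group-level inter-regional association matrix
#'
#' Symmetric region-by-region matrix of Pearson correlations of age-adjusted
#' thickness within one group, with the diagonal forced to zero. This is the
#' weighted object that [thresholdByDensity()] and [thresholdAbsolute()] turn
#' into binary structural covariance networks.
#'
#' @slot r symmetric numeric matrix, zero diagonal, off-diagonal in `[-1, 1]`,
#'   dimnames carrying the region columns.
#' @slot group group label the matrix was computed from.
#' @slot nSubjects number of subjects that entered the correlations.
#'
#' @seealso [associationMatrix()], [densitySweep()]
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  slots = c(r = "matrix", group = "character", nSubjects = "integer"))

setValidity("AssociationMatrix", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r)) return("matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    msg <- c(msg, "matrix needs matching row/column region names")
  if (max(abs(r - t(r))) > 1e-10)
    msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(r)) > 0))
    msg <- c(msg, "diagonal must be exactly zero")
  off <- r[row(r) != col(r)]
  if (any(abs(off) > 1 + 1e-12))
    msg <- c(msg, "off-diagonal entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Binary undirected network at a stated density
#'
#' 0/1 adjacency matrix with zero diagonal. `density` is the edge count
#' divided by the maximum possible `n(n-1)/2`; for density-thresholded
#' networks the realized edge count equals `round(density * n(n-1)/2)`
#' (half away from zero).
#'
#' @slot adjacency symmetric integer 0/1 matrix, zero diagonal, region
#'   dimnames.
#' @slot density fraction of possible edges present, in `(0, 1]`.
#'
#' @seealso [thresholdByDensity()], [asIgraph()], [globalMetrics()]
#' @exportClass BinaryNetwork
setClass("BinaryNetwork",
  slots = c(adjacency = "matrix", density = "numeric"))

setValidity("BinaryNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!all(a %in% c(0L, 1L)))
    msg <- c(msg, "entries must be 0 or 1")
  if (!identical(a, t(a)))
    msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(a) != 0))
    msg <- c(msg, "no self-loops: diagonal must be zero")
  d <- object@density
  if (length(d) != 1L || is.na(d) || d < 0 || d > 1)
    msg <- c(msg, "density must be a single value in [0, 1]")
  if (length(d) == 1L && !is.na(d) && d == 0 && sum(a) > 0)
    msg <- c(msg, "density 0 requires an edgeless network")
  npair <- nrow(a) * (nrow(a) - 1L) / 2
  if (length(d) == 1L && !is.na(d) && npair > 0 &&
      sum(a) / 2 != roundHalfUp(d * npair))
    msg <- c(msg, "edge count must equal round(density * n(n-1)/2)")
  if (length(msg)) msg else TRUE
})

#' A graph metric evaluated along the density sweep
#'
#' Holds the per-density values of one metric (one row for a global metric,
#' one row per region for a nodal metric) together with the trapezoidal area
#' under the curve over the density grid, the threshold-free summary used for
#' group comparison.
#'
#' @slot metric metric name.
#' @slot densities the density grid the sweep was evaluated on.
#' @slot values numeric matrix, `1 x n_densities` (global) or
#'   `n_regions x n_densities` (nodal).
#' @slot auc per-row trapezoidal integral over `densities` (`NA` when the
#'   grid has fewer than two points).
#'
#' @seealso [metricCurve()], [aucOverDensities()]
#' @exportClass MetricCurve
setClass("MetricCurve",
  slots = c(metric = "character", densities = "numeric",
            values = "matrix", auc = "numeric"))

setValidity("MetricCurve", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@densities))
    msg <- c(msg, "values must have one column per density")
  if (length(object@auc) != nrow(object@values))
    msg <- c(msg, "auc must have one entry per row of values")
  if (length(msg)) msg else TRUE
})

#' Permutation inference on a between-group metric difference
#'
#' Result of [permutationTest()]: the observed group difference
#' (groupA minus groupB, groups in sorted label order) per density and for
#' the AUC, the permutation-null mean and 2.5/97.5 percentile bounds,
#' two-tailed p-values with the +1 small-sample correction, and - for nodal
#' metrics - Benjamini-Hochberg adjusted p-values across regions.
#'
#' @slot metric metric name.
#' @slot nodal whether the statistic is per-region.
#' @slot densities density grid.
#' @slot observedDiff rows = regions (nodal) or a single row (global).
#' @slot observedAUC per-row AUC of the observed difference curve.
#' @slot nullMean,nullLower,nullUpper permutation-null summaries, same shape
#'   as `observedDiff`.
#' @slot aucNullMean,aucNullLower,aucNullUpper null summaries for the AUC.
#' @slot pPerDensity,pAUC two-tailed permutation p-values.
#' @slot fdrPerDensity,fdrAUC BH-adjusted p-values across regions (nodal
#'   metrics; empty for global metrics).
#' @slot nPerm number of permutations.
#' @slot seed seed the label shuffles were drawn from.
#'
#' @exportClass PermutationResult
setClass("PermutationResult",
  slots = c(metric = "character", nodal = "logical", densities = "numeric",
            observedDiff = "matrix", observedAUC = "numeric",
            nullMean = "matrix", nullLower = "matrix", nullUpper = "matrix",
            aucNullMean = "numeric", aucNullLower = "numeric",
            aucNullUpper = "numeric",
            pPerDensity = "matrix", pAUC = "numeric",
            fdrPerDensity = "matrix", fdrAUC = "numeric",
            nPerm = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (any(object@pPerDensity <= 0) || any(object@pPerDensity > 1) ||
      any(object@pAUC <= 0) || any(object@pAUC > 1))
    msg <- c(msg, "permutation p-values must lie in (0, 1]")
  if (any(object@nullLower > object@nullUpper))
    msg <- c(msg, "null percentile bounds must be ordered")
  if (length(object@fdrPerDensity) &&
      any(object@fdrPerDensity + 1e-12 < object@pPerDensity))
    msg <- c(msg, "FDR-adjusted p-values cannot undercut raw p-values")
  if (length(msg)) msg else TRUE
})

#' Hub set of a binary network
#'
#' Regions whose betweenness centrality is at least `k` standard deviations
#' above the network mean (`k = 2` by default, inclusive threshold). The
#' standard deviation is taken over the full node set (population form by
#' default, since the atlas is a census of regions, not a sample).
#'
#' @slot group group label the network belongs to ("" if unspecified).
#' @slot density density the network was thresholded at.
#' @slot hubs hub region names, sorted by decreasing betweenness.
#' @slot betweenness the full named betweenness vector the rule was applied
#'   to.
#' @slot bMean,bSd,threshold mean, standard deviation and `mean + k * sd`.
#' @slot k the z-threshold multiplier.
#'
#' @seealso [identifyHubs()], [compareHubs()]
#' @exportClass HubReport
setClass("HubReport",
  slots = c(group = "character", density = "numeric", hubs = "character",
            betweenness = "numeric", bMean = "numeric", bSd = "numeric",
            threshold = "numeric", k = "numeric"))

setValidity("HubReport", function(object) {
  msg <- character()
  if (!all(object@hubs %in% names(object@betweenness)))
    msg <- c(msg, "hubs must be named in the betweenness vector")
  if (object@bSd > 0 &&
      any(object@betweenness[object@hubs] + 1e-12 < object@threshold))
    msg <- c(msg, "every hub's betweenness must reach the threshold")
  if (length(msg)) msg else TRUE
})

#' Generative configuration for a synthetic two-group cohort
#'
#' Parameters of the linear factor model used by [generateCohort()]:
#' thickness of subject \eqn{s} in region \eqn{r} is
#' \deqn{t_{sr} = \mu_r + \beta_r \, \mathrm{age}_s + \sum_k L_{rk} f_{sk} +
#'   \epsilon_{sr}}
#' with standard-normal factor scores \eqn{f} and Gaussian noise
#' \eqn{\epsilon}. The loading matrices (one per group) set the
#' inter-regional covariance communities; unequal loadings plant a group
#' contrast; a row loading on every factor plants a connector hub.
#'
#' @slot nPerGroup subjects per group (study-sized default 23).
#' @slot atlas the [BrainAtlas] the cohort is simulated on.
#' @slot nFactors number of latent factors.
#' @slot loadingsA,loadingsB regions-by-factors loading matrices (mm).
#' @slot regionMeans per-region mean thickness (mm).
#' @slot ageMean,ageSd,ageRange Gaussian age distribution (years), truncated
#'   to `ageRange`.
#' @slot ageSlopes per-region thickness-on-age slope (mm/year).
#' @slot noiseSd residual noise standard deviation (mm).
#' @slot seed master seed; age, factor scores and noise use substreams
#'   derived from it.
#'
#' @seealso [cohortConfig()], [nullConfig()], [effectConfig()], [hubConfig()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  slots = c(nPerGroup = "integer", atlas = "BrainAtlas",
            nFactors = "integer", loadingsA = "matrix", loadingsB = "matrix",
            regionMeans = "numeric", ageMean = "numeric", ageSd = "numeric",
            ageRange = "numeric", ageSlopes = "numeric", noiseSd = "numeric",
            seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  n <- nRegions(object@atlas)
  if (object@nPerGroup < 3L)
    msg <- c(msg, "nPerGroup must be at least 3")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be nonnegative")
  for (nm in c("loadingsA", "loadingsB")) {
    L <- slot(object, nm)
    if (!identical(dim(L), c(n, as.integer(object@nFactors))))
      msg <- c(msg, sprintf("%s must be %d regions x %d factors", nm, n,
                            object@nFactors))
  }
  if (length(object@regionMeans) != n || length(object@ageSlopes) != n)
    msg <- c(msg, "regionMeans and ageSlopes must have one entry per region")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be an increasing pair of years")
  if (length(msg)) msg else TRUE
})
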