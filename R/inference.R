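#' @include metrics.R
NULL

globalMetricNames <- c("clustering", "path_length", "global_efficiency",
                       "local_efficiency", "transitivity", "modularity",
                       "gamma", "lambda", "sigma")
nodalMetricNames <- c("degree", "betweenness", "clustering",
                      "local_efficiency")

# Returns a function(g) -> scalar (global) or named n-vector (nodal).
metricEvaluator <- function(metric, nodal, normalize = TRUE, nRandom = 20L,
                            seed = 1L, swapsPerEdge = 10L) {
  if (nodal) {
    if (!(metric %in% nodalMetricNames))
      stopf("unknown nodal metric '%s' (available: %s)", metric,
            paste(nodalMetricNames, collapse = ", "))
    base <- switch(metric,
      degree = function(g) igraph::degree(g),
      betweenness = btwVec,
      clustering = cpLocal,
      local_efficiency = elocVec)
    if (normalize) function(g) normalizeNodal(base(g)) else base
  } else {
    if (!(metric %in% globalMetricNames))
      stopf("unknown global metric '%s' (available: %s)", metric,
            paste(globalMetricNames, collapse = ", "))
    switch(metric,
      clustering = function(g) mean(cpLocal(g)),
      path_length = lpCore,
      global_efficiency = function(g) igraph::global_efficiency(g),
      local_efficiency = function(g) mean(elocVec(g)),
      transitivity = transCore,
      modularity = function(g) modCore(g, seed)$q,
      gamma = function(g) swiCore(g, nRandom, seed, swapsPerEdge)[["gamma"]],
      lambda = function(g) swiCore(g, nRandom, seed, swapsPerEdge)[["lambda"]],
      sigma = function(g) swiCore(g, nRandom, seed, swapsPerEdge)[["sigma"]])
  }
}

#' Evaluate one metric along a density sweep
#'
#' @param networks list of [BinaryNetwork] from one [densitySweep()].
#' @param metric one of `"clustering"`, `"path_length"`,
#'   `"global_efficiency"`, `"local_efficiency"`, `"transitivity"`,
#'   `"modularity"`, `"gamma"`, `"lambda"`, `"sigma"` (global scope) or
#'   `"degree"`, `"betweenness"`, `"clustering"`, `"local_efficiency"`
#'   (nodal scope).
#' @param nodal evaluate per region (default `TRUE` for degree and
#'   betweenness, `FALSE` otherwise).
#' @param normalize divide nodal values by their network mean
#'   ([normalizeNodal()]); ignored for global metrics.
#' @param nRandom,seed,swapsPerEdge settings for seed-dependent metrics
#'   (modularity restarts; rewired nulls of gamma/lambda/sigma).
#' @return a [MetricCurve]; its `auc` holds the trapezoidal integral over
#'   the density grid (`NA` with a single grid point).
#' @export
metricCurve <- function(networks, metric,
                        nodal = metric %in% c("degree", "betweenness"),
                        normalize = TRUE, nRandom = 20L, seed = 1L,
                        swapsPerEdge = 10L) {
  densities <- vapply(networks, networkDensity, numeric(1))
  ev <- metricEvaluator(metric, nodal, normalize, nRandom, seed, swapsPerEdge)
  vals <- vapply(networks, function(net) ev(asIgraph(net)),
                 numeric(if (nodal) nrow(adjacency(networks[[1]])) else 1L))
  vals <- matrix(vals, ncol = length(networks))
  if (nodal) rownames(vals) <- rownames(adjacency(networks[[1]]))
  auc <- if (length(densities) >= 2L)
    apply(vals, 1L, function(y) pracma::trapz(densities, y))
  else rep(NA_real_, nrow(vals))
  methods::new("MetricCurve", metric = metric, densities = densities,
               values = vals, auc = unname(auc))
}

#' Area under a metric curve over the density grid
#'
#' Trapezoidal integration of metric values against density, the
#' threshold-free summary used for group comparison.
#'
#' @param x a [MetricCurve], or a numeric vector/matrix of values (rows
#'   integrated separately).
#' @param densities grid the values sit on (taken from `x` when it is a
#'   [MetricCurve]); at least 2 points.
#' @return numeric vector of AUCs (length = number of rows).
#' @examples
#' aucOverDensities(rep(2, 21), densityGrid())  # 0.4 * 2
#' @export
aucOverDensities <- function(x, densities = NULL) {
  if (methods::is(x, "MetricCurve")) {
    densities <- x@densities
    x <- x@values
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (length(densities) != ncol(x))
    stopf("need one density per value column")
  if (length(densities) < 2L)
    stopf("AUC needs at least 2 grid points")
  unname(apply(x, 1L, function(y) pracma::trapz(densities, y)))
}

setMethod("show", "MetricCurve", function(object) {
  cat(sprintf("MetricCurve '%s': %s over %d densities [%.3g, %.3g]\n",
              object@metric,
              if (nrow(object@values) > 1L)
                sprintf("%d regions", nrow(object@values)) else "global",
              length(object@densities), min(object@densities),
              max(object@densities)))
  if (nrow(object@values) == 1L)
    cat(sprintf("  AUC = %.6g\n", object@auc))
})

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, as applied across
#' the atlas regions for nodal statistics.
#'
#' @param p p-values in `(0, 1]`.
#' @return adjusted p-values, elementwise `>= p`.
#' @examples
#' fdrBH(c(0.005, 0.5))  # 0.01, 0.5
#' @export
fdrBH <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pooled two-sample t-test from summary statistics
#'
#' The classical equal-variance t-test computed from group means, standard
#' deviations and sizes, as used for demographic comparisons when only
#' summaries are available.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return `list(t = , df = , p = )` with a two-tailed p-value.
#' @examples
#' # age comparison of two groups of 23:
#' summaryTTest(42.04, 10.52, 23, 36.96, 6.23, 23)$p  # ~0.052
#' @export
summaryTTest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stopf("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-region group comparison of thickness by GLM
#'
#' Ordinary least squares of each region's thickness on intercept, group and
#' age; reports the age-adjusted group effect (groupA minus groupB, groups
#' in sorted label order), its t statistic, two-tailed p, and BH-FDR across
#' regions.
#'
#' @param x a [ThicknessExperiment] with two groups, >= 3 subjects each.
#' @return `data.frame` with columns `region`, `group_effect`, `t`, `p`,
#'   `fdr`.
#' @export
regionGLM <- function(x) {
  g <- factor(groupLabels(x))
  if (nlevels(g) != 2L)
    stopf("regionGLM needs exactly two groups (got %d)", nlevels(g))
  if (any(table(g) < 3L))
    stopf("each group needs at least 3 subjects")
  Y <- thicknessValues(x)
  X <- stats::model.matrix(~ g + subjectAges(x))
  if (qr(X)$rank < ncol(X))
    stopf("rank-deficient design (is age confounded with group?)")
  fit <- stats::lm.fit(X, Y)
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(fit$residuals^2) / dfres
  cgg <- chol2inv(chol(crossprod(X)))[2L, 2L]
  # column 2 codes level-2 minus level-1; flip to the groupA - groupB sign
  effect <- -fit$coefficients[2L, ]
  tstat <- effect / sqrt(sigma2 * cgg)
  p <- 2 * stats::pt(-abs(tstat), dfres)
  data.frame(region = colnames(Y), group_effect = unname(effect),
             t = unname(tstat), p = unname(p), fdr = fdrBH(unname(p)),
             stringsAsFactors = FALSE)
}

# ---- permutation machinery -------------------------------------------------

# Metric values along a nested sweep for one group, built incrementally:
# the edge ranking is computed once and each density only adds the new
# edges to the running igraph object.
sweepValues <- function(Xg, ageg, grid, ev, nodal, rankBy, residualize) {
  R <- if (residualize == "pergroup") residMatrix(Xg, ageg) else Xg
  r <- stats::cor(R)
  diag(r) <- 0
  n <- ncol(r)
  npair <- n * (n - 1L) / 2
  ord <- edgeOrder(r, rankBy)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  prev <- 0L
  vals <- matrix(NA_real_, if (nodal) n else 1L, length(grid))
  for (k in seq_along(grid)) {
    K <- roundHalfUp(grid[k] * npair)
    if (K > prev) {
      idx <- (prev + 1L):K
      g <- igraph::add_edges(g, rbind(ord$i[idx], ord$j[idx]))
      prev <- K
    }
    vals[, k] <- ev(g)
  }
  if (nodal) rownames(vals) <- colnames(Xg)
  vals
}

diffStat <- function(X, age, labels, levels, grid, ev, nodal, rankBy,
                     residualize) {
  a <- labels == levels[1L]
  vA <- sweepValues(X[a, , drop = FALSE], age[a], grid, ev, nodal, rankBy,
                    residualize)
  vB <- sweepValues(X[!a, , drop = FALSE], age[!a], grid, ev, nodal, rankBy,
                    residualize)
  vA - vB
}

#' Permutation test of a between-group metric difference
#'
#' The observed statistic is the difference (groupA minus groupB, groups in
#' sorted label order) of the metric evaluated through the full pipeline:
#' age residualization within each group, Pearson association matrix,
#' density thresholding over the grid, metric per density, and trapezoidal
#' AUC. For each permutation, subject group labels are reassigned at random
#' (group sizes preserved) and the entire pipeline re-run, so the null
#' distribution reflects group-level covariance estimation, not just metric
#' noise. Two-tailed p-values use the small-sample correction
#' `(1 + #permutations at least as extreme) / (nPerm + 1)`, per density and
#' for the AUC. For nodal metrics, Benjamini-Hochberg adjustment is applied
#' across regions separately per density and for the AUC.
#'
#' @param x a [ThicknessExperiment] with two groups, >= 4 subjects each.
#' @param metric metric name, see [metricCurve()].
#' @param grid density grid.
#' @param nPerm number of permutations (the standard choice is 1000).
#' @param seed integer seed for the label shuffles.
#' @param nodal,normalize see [metricCurve()].
#' @param residualize `"pergroup"` (default: age adjusted within each
#'   (re)labelled group, matching per-group matrix construction) or
#'   `"pooled"` (adjusted once across all subjects before permutation).
#' @param rankBy edge ranking, see [thresholdByDensity()].
#' @param nRandom,swapsPerEdge settings for seed-dependent metrics.
#' @return a [PermutationResult].
#' @export
permutationTest <- function(x, metric, grid = densityGrid(), nPerm = 1000L,
                            seed = 1L,
                            nodal = metric %in% c("degree", "betweenness"),
                            normalize = TRUE,
                            residualize = c("pergroup", "pooled"),
                            rankBy = c("signed", "absolute"),
                            nRandom = 20L, swapsPerEdge = 10L) {
  residualize <- match.arg(residualize)
  rankBy <- match.arg(rankBy)
  labels <- groupLabels(x)
  levels <- sort(unique(labels))
  if (length(levels) != 2L)
    stopf("permutationTest needs exactly two groups (got %d)", length(levels))
  if (any(table(labels) < 4L))
    stopf("each group needs at least 4 subjects")
  if (nPerm < 100L)
    stopf("use at least 100 permutations")
  X <- thicknessValues(x)
  age <- subjectAges(x)
  if (residualize == "pooled") X <- residMatrix(X, age)
  evalSeed <- deriveSeeds(seed, 2L)
  ev <- metricEvaluator(metric, nodal, normalize, nRandom, evalSeed[1L],
                        swapsPerEdge)

  obs <- diffStat(X, age, labels, levels, grid, ev, nodal, rankBy,
                  residualize)
  m <- nrow(obs)
  obsAUC <- aucOverDensities(obs, grid)

  nullD <- array(NA_real_, c(nPerm, m, length(grid)))
  nullAUC <- matrix(NA_real_, nPerm, m)
  set.seed(evalSeed[2L])
  for (b in seq_len(nPerm)) {
    perm <- sample(labels)
    d <- diffStat(X, age, perm, levels, grid, ev, nodal, rankBy, residualize)
    nullD[b, , ] <- d
    nullAUC[b, ] <- aucOverDensities(d, grid)
  }

  eps <- 1e-12
  pD <- matrix(NA_real_, m, length(grid), dimnames = dimnames(obs))
  for (k in seq_along(grid)) for (i in seq_len(m))
    pD[i, k] <- (1 + sum(abs(nullD[, i, k]) >= abs(obs[i, k]) - eps)) /
      (nPerm + 1)
  pAUC <- vapply(seq_len(m), function(i)
    (1 + sum(abs(nullAUC[, i]) >= abs(obsAUC[i]) - eps)) / (nPerm + 1),
    numeric(1))

  qs <- function(a, probs) apply(a, seq_along(dim(a))[-1L], stats::quantile,
                                 probs = probs, names = FALSE)
  keepNames <- function(mat) {
    mat <- matrix(mat, m, length(grid))
    dimnames(mat) <- dimnames(obs)
    mat
  }
  fdrD <- if (nodal) apply(pD, 2L, fdrBH) else
    matrix(numeric(0), 0L, 0L)
  if (nodal) dimnames(fdrD) <- dimnames(pD)
  methods::new("PermutationResult",
    metric = metric, nodal = nodal, densities = grid,
    observedDiff = obs, observedAUC = obsAUC,
    nullMean = keepNames(apply(nullD, c(2L, 3L), mean)),
    nullLower = keepNames(qs(nullD, 0.025)),
    nullUpper = keepNames(qs(nullD, 0.975)),
    aucNullMean = colMeans(nullAUC),
    aucNullLower = apply(nullAUC, 2L, stats::quantile, 0.025, names = FALSE),
    aucNullUpper = apply(nullAUC, 2L, stats::quantile, 0.975, names = FALSE),
    pPerDensity = pD, pAUC = pAUC,
    fdrPerDensity = fdrD,
    fdrAUC = if (nodal) fdrBH(pAUC) else numeric(0),
    nPerm = as.integer(nPerm), seed = as.integer(seed))
}

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult '%s' (%s): %d permutations over %d densities\n",
    object@metric, if (object@nodal) "nodal" else "global",
    object@nPerm, length(object@densities)))
  if (!object@nodal) {
    cat(sprintf("  observed AUC diff (A - B) = %.6g, p = %.4g\n",
                object@observedAUC, object@pAUC))
    cat(sprintf("  densities with p < 0.05: %d of %d\n",
                sum(object@pPerDensity < 0.05), length(object@densities)))
  } else {
    cat(sprintf("  regions with AUC FDR < 0.05: %d of %d\n",
                sum(object@fdrAUC < 0.05), length(object@fdrAUC)))
  }
})
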