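#' @include inference.R hubs.R synthetic.R
NULL

#' Simulate a cohort and write it as a TSV bundle
#'
#' Writes `thickness.tsv` and `covariates.tsv` (the formats
#' [readThicknessTable()] consumes), the generating configuration as
#' `cohort_config.yaml`, and a small `manifest.json`. Reruns with the same
#' configuration produce byte-identical files.
#'
#' @param config a [CohortConfig].
#' @param dir output directory (created if missing).
#' @return invisibly, the generated [ThicknessExperiment].
#' @export
simulateCohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  te <- generateCohort(config)
  writeThicknessTable(te, file.path(dir, "thickness.tsv"),
                      file.path(dir, "covariates.tsv"))
  writeCohortConfig(config, file.path(dir, "cohort_config.yaml"))
  jsonlite::write_json(list(
    tool = "scnet::simulateCohort",
    scnet_version = as.character(utils::packageVersion("scnet")),
    atlas = config@atlas@name, n_per_group = config@nPerGroup,
    seed = config@seed,
    files = c("thickness.tsv", "covariates.tsv", "cohort_config.yaml")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(te)
}

writeCurveTSV <- function(values, densities, auc, path,
                          rowLabel = "metric") {
  df <- data.frame(rownames(values), stringsAsFactors = FALSE)
  colnames(df) <- rowLabel
  for (k in seq_along(densities))
    df[[sprintf("d%.2f", densities[k])]] <- fmtNum(values[, k])
  df[["auc"]] <- fmtNum(auc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Run the full structural covariance network analysis
#'
#' End-to-end group comparison on one cohort: per-group age-adjusted
#' association matrices, minimum unfragmented density, density sweeps,
#' global and nodal metric curves with AUC, permutation tests (per density
#' and AUC, BH-FDR across regions for nodal metrics), betweenness hub
#' reports at `Dmin`, and a per-region thickness GLM. All tables are
#' written to `outDir` along with a JSON manifest; outputs are
#' byte-reproducible given the same inputs and seed.
#'
#' @param x a [ThicknessExperiment] with exactly two groups.
#' @param outDir output directory (created if missing).
#' @param grid density grid, see [densityGrid()].
#' @param nPerm permutations per test (standard: 1000).
#' @param seed master seed; every stochastic step uses a subseed derived
#'   from it.
#' @param permMetricsGlobal global metrics to permutation-test. The
#'   rewired-null metrics (`gamma`, `lambda`, `sigma`) are excluded by
#'   default because each permutation would re-rewire the ensemble; pass
#'   them explicitly (with reduced `nPerm`/`nRandom`) if needed.
#' @param permMetricsNodal nodal metrics to permutation-test.
#' @param hubK hub z-threshold multiplier, see [identifyHubs()].
#' @param alpha significance level used in the summary counts.
#' @param nRandom rewired ensemble size for `gamma`/`lambda`/`sigma`
#'   curves.
#' @param residualize,rankBy pipeline options, see [permutationTest()].
#' @param writeAdjacency also write the thresholded adjacency matrix of
#'   every density as TSV.
#' @return invisibly, a list with elements `association` (per group),
#'   `dmin`, `globalCurves`, `nodalCurves`, `permutation` (per metric),
#'   `hubs` (per group plus `comparison`), `regionGLM`, and `manifest`.
#' @export
runSCNPipeline <- function(x, outDir, grid = densityGrid(), nPerm = 1000L,
                           seed = 1L,
                           permMetricsGlobal = c("clustering", "path_length",
                             "global_efficiency", "local_efficiency",
                             "transitivity", "modularity"),
                           permMetricsNodal = c("clustering", "degree",
                             "betweenness", "local_efficiency"),
                           hubK = 2, alpha = 0.05, nRandom = 20L,
                           residualize = c("pergroup", "pooled"),
                           rankBy = c("signed", "absolute"),
                           writeAdjacency = TRUE) {
  residualize <- match.arg(residualize)
  rankBy <- match.arg(rankBy)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  labels <- groupLabels(x)
  groups <- sort(unique(labels))
  if (length(groups) != 2L)
    stopf("the pipeline needs exactly two groups (got: %s)",
          paste(groups, collapse = ", "))

  nTests <- length(permMetricsGlobal) + length(permMetricsNodal)
  subseeds <- deriveSeeds(seed, nTests + 2L)

  # association matrices and sweeps per group
  assoc <- lapply(groups, function(g) {
    te <- x[, labels == g]
    if (residualize == "pooled") {
      res <- residMatrix(thicknessValues(x), subjectAges(x))
      te <- ThicknessExperiment(res[labels == g, , drop = FALSE],
                                groupLabels(x)[labels == g],
                                subjectAges(x)[labels == g], atlas(x),
                                residualized = TRUE)
    }
    associationMatrix(te)
  })
  names(assoc) <- groups
  for (g in groups)
    writeMatrixTSV(assoc[[g]], file.path(outDir,
                                         sprintf("association_%s.tsv", g)))

  dmin <- minUnfragmentedDensity(assoc[[1L]], assoc[[2L]], grid, rankBy)
  sweeps <- lapply(assoc, densitySweep, grid = grid, rankBy = rankBy)
  if (writeAdjacency)
    for (g in groups)
      for (net in sweeps[[g]])
        writeMatrixTSV(net, file.path(outDir,
          sprintf("adjacency_%s_d%.2f.tsv", g, networkDensity(net))))

  # metric curves
  globalCurves <- lapply(groups, function(g) {
    vals <- lapply(globalMetricNames, function(mn)
      metricCurve(sweeps[[g]], mn, nodal = FALSE, nRandom = nRandom,
                  seed = subseeds[nTests + 1L]))
    v <- do.call(rbind, lapply(vals, methods::slot, "values"))
    rownames(v) <- globalMetricNames
    auc <- vapply(vals, methods::slot, numeric(1), "auc")
    writeCurveTSV(v, grid, auc,
                  file.path(outDir, sprintf("global_metrics_%s.tsv", g)))
    list(values = v, auc = stats::setNames(auc, globalMetricNames))
  })
  names(globalCurves) <- groups

  nodalCurves <- lapply(groups, function(g) {
    out <- lapply(nodalMetricNames, function(mn) {
      cu <- metricCurve(sweeps[[g]], mn, nodal = TRUE)
      writeCurveTSV(cu@values, grid, cu@auc,
        file.path(outDir, sprintf("nodal_%s_%s.tsv", mn, g)),
        rowLabel = "region")
      cu
    })
    names(out) <- nodalMetricNames
    out
  })
  names(nodalCurves) <- groups

  # permutation inference
  permResults <- list()
  si <- 0L
  globRows <- list()
  for (mn in permMetricsGlobal) {
    si <- si + 1L
    pr <- permutationTest(x, mn, grid, nPerm, seed = subseeds[si],
                          nodal = FALSE, residualize = residualize,
                          rankBy = rankBy, nRandom = nRandom)
    permResults[[mn]] <- pr
    globRows[[mn]] <- data.frame(
      metric = mn,
      density = c(grid, NA),
      observed_diff = c(pr@observedDiff[1L, ], pr@observedAUC),
      null_lower = c(pr@nullLower[1L, ], pr@aucNullLower),
      null_upper = c(pr@nullUpper[1L, ], pr@aucNullUpper),
      p = c(pr@pPerDensity[1L, ], pr@pAUC),
      summary = c(rep("per_density", length(grid)), "auc"),
      stringsAsFactors = FALSE)
  }
  if (length(globRows)) {
    gdf <- do.call(rbind, globRows)
    for (cn in c("observed_diff", "null_lower", "null_upper", "p"))
      gdf[[cn]] <- fmtNum(gdf[[cn]])
    utils::write.table(gdf, file.path(outDir, "permutation_global.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  for (mn in permMetricsNodal) {
    si <- si + 1L
    pr <- permutationTest(x, mn, grid, nPerm, seed = subseeds[si],
                          nodal = TRUE, residualize = residualize,
                          rankBy = rankBy)
    permResults[[paste0("nodal_", mn)]] <- pr
    ndf <- data.frame(
      region = rownames(pr@observedDiff),
      auc_observed_diff = fmtNum(pr@observedAUC),
      auc_p = fmtNum(pr@pAUC),
      auc_fdr = fmtNum(pr@fdrAUC),
      n_densities_sig = colSums(t(pr@fdrPerDensity) < alpha),
      stringsAsFactors = FALSE)
    utils::write.table(ndf,
      file.path(outDir, sprintf("permutation_nodal_%s.tsv", mn)),
      sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }

  # hubs at Dmin
  dminIdx <- which(abs(grid - dmin) < 1e-9)[1L]
  hubs <- lapply(groups, function(g)
    identifyHubs(sweeps[[g]][[dminIdx]], k = hubK, group = g))
  names(hubs) <- groups
  for (g in groups)
    writeHubReport(hubs[[g]], file.path(outDir,
                                        sprintf("hubs_%s.json", g)))
  hubs$comparison <- compareHubs(hubs[[1L]], hubs[[2L]])

  glm <- regionGLM(x)
  glmOut <- glm
  for (cn in c("group_effect", "t", "p", "fdr"))
    glmOut[[cn]] <- fmtNum(glmOut[[cn]])
  utils::write.table(glmOut, file.path(outDir, "region_glm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  manifest <- list(
    tool = "scnet::runSCNPipeline",
    scnet_version = as.character(utils::packageVersion("scnet")),
    atlas = atlas(x)@name,
    groups = as.list(stats::setNames(as.integer(table(labels)[groups]),
                                     groups)),
    grid = list(d_min = grid[1L], d_max = grid[length(grid)],
                n_densities = length(grid)),
    dmin_unfragmented = dmin,
    n_perm = as.integer(nPerm), seed = as.integer(seed),
    hub_k = hubK, alpha = alpha, n_random = as.integer(nRandom),
    residualize = residualize, rank_by = rankBy,
    perm_metrics_global = as.list(permMetricsGlobal),
    perm_metrics_nodal = as.list(permMetricsNodal))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(association = assoc, dmin = dmin,
                 globalCurves = globalCurves, nodalCurves = nodalCurves,
                 permutation = permResults, hubs = hubs, regionGLM = glm,
                 manifest = manifest))
}
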