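#' @include io.R
NULL

# OLS residuals of every column of X on [1, age]; qr once for all regions.
residMatrix <- function(X, age) {
  qr.resid(qr(cbind(1, age)), X)
}

#' @rdname residualizeAge
#' @export
setMethod("residualizeAge", "ThicknessExperiment", function(x) {
  if (ncol(x) < 3L)
    stopf("age residualization needs at least 3 subjects (got %d)", ncol(x))
  X <- thicknessValues(x)
  age <- subjectAges(x)
  if (stats::sd(age) == 0) {
    warnf("age is constant; returning mean-centred thickness instead of age residuals")
    res <- scale(X, center = TRUE, scale = FALSE)[, , drop = FALSE]
  } else {
    res <- residMatrix(X, age)
  }
  dimnames(res) <- dimnames(X)
  ThicknessExperiment(res, groupLabels(x), age, atlas(x),
                      subjectIds = rownames(X), residualized = TRUE)
})

#' @rdname associationMatrix
#' @param residualize adjust for age internally (default). Skipped
#'   automatically when `x` is already residualized.
#' @export
setMethod("associationMatrix", "ThicknessExperiment",
          function(x, residualize = TRUE) {
  grp <- unique(groupLabels(x))
  if (length(grp) != 1L)
    stopf("associationMatrix expects subjects of a single group (got: %s)",
          paste(grp, collapse = ", "))
  if (ncol(x) < 4L)
    stopf("at least 4 subjects are needed to correlate regions (got %d)",
          ncol(x))
  already <- isTRUE(S4Vectors::metadata(x)$residualized)
  if (residualize && !already) x <- residualizeAge(x)
  X <- thicknessValues(x)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stopf("region(s) with zero variance: %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  r <- stats::cor(X)
  diag(r) <- 0
  methods::new("AssociationMatrix", r = r, group = grp,
               nSubjects = ncol(x))
})

#' @rdname assocValues
#' @export
setMethod("assocValues", "AssociationMatrix", function(x) x@r)

setMethod("show", "AssociationMatrix", function(object) {
  off <- object@r[upper.tri(object@r)]
  cat(sprintf(
    "AssociationMatrix (%d x %d) for group '%s' (n = %d subjects)\n",
    nrow(object@r), ncol(object@r), object@group, object@nSubjects))
  cat(sprintf("  off-diagonal r: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
})

#' Density grid for the threshold sweep
#'
#' The default sweep runs from 0.1 to 0.5 in steps of 0.02 (21 points):
#' below ~0.1 group networks tend to fragment, above 0.5 binary cortical
#' networks lose biological interpretability.
#'
#' @param dMin,dMax,step grid parameters, all in `(0, 1]`.
#' @return numeric vector of densities.
#' @examples
#' length(densityGrid())  # 21
#' @export
densityGrid <- function(dMin = 0.1, dMax = 0.5, step = 0.02) {
  if (!(dMin > 0 && dMin < dMax && dMax <= 1 && step > 0))
    stopf("need 0 < dMin < dMax <= 1 and step > 0")
  g <- seq(dMin, dMax + step * 1e-8, by = step)
  g[g <= dMax + step * 1e-8]
}

# Order of upper-triangle entries for edge selection: decreasing value,
# ties broken by lexicographic (i, j) so thresholding is reproducible
# across platforms. rankBy = "absolute" ranks by |r| instead of signed r.
edgeOrder <- function(r, rankBy = c("signed", "absolute")) {
  rankBy <- match.arg(rankBy)
  n <- nrow(r)
  up <- upperPairs(n)
  v <- r[up$flat]
  if (rankBy == "absolute") v <- abs(v)
  o <- order(-v, up$i, up$j)
  list(i = up$i[o], j = up$j[o], flat = up$flat[o], n = n)
}

adjacencyFromEdges <- function(ord, K, labels) {
  a <- matrix(0L, ord$n, ord$n, dimnames = list(labels, labels))
  sel <- ord$flat[seq_len(K)]
  a[sel] <- 1L
  a + t(a)
}

#' Threshold an association matrix at a target density
#'
#' Keeps the `K = round(D * n(n-1)/2)` largest off-diagonal correlations
#' (rounding half away from zero) as edges. By default ranking is by signed
#' value, so negative correlations only enter once all positive ones are
#' used; set `rankBy = "absolute"` to rank by magnitude. Ties at the cut are
#' broken toward the lexicographically smaller region pair.
#'
#' @param m an [AssociationMatrix].
#' @param density target density in `(0, 1]`.
#' @param rankBy `"signed"` (default) or `"absolute"`.
#' @return a [BinaryNetwork] with exactly `K` edges.
#' @seealso [densitySweep()], [thresholdAbsolute()]
#' @export
thresholdByDensity <- function(m, density, rankBy = c("signed", "absolute")) {
  if (!(density > 0 && density <= 1))
    stopf("density must be in (0, 1]")
  r <- assocValues(m)
  n <- nrow(r)
  npair <- n * (n - 1L) / 2
  K <- roundHalfUp(density * npair)
  if (K == 0L)
    stopf("density %.4g keeps no edges on %d regions (empty network)",
          density, n)
  ord <- edgeOrder(r, rankBy)
  methods::new("BinaryNetwork",
               adjacency = adjacencyFromEdges(ord, K, rownames(r)),
               density = density)
}

#' Threshold an association matrix at an absolute correlation
#'
#' The secondary rule: an edge wherever `r_ij > r0` (strict). Realized
#' densities then differ between groups, which is why matched-density
#' thresholding ([thresholdByDensity()]) is the primary path for group
#' comparison.
#'
#' @param m an [AssociationMatrix].
#' @param r0 correlation cutoff in `(-1, 1)`.
#' @return a [BinaryNetwork]; its `density` is the realized edge fraction.
#' @export
thresholdAbsolute <- function(m, r0) {
  if (!(r0 > -1 && r0 < 1)) stopf("r0 must be in (-1, 1)")
  r <- assocValues(m)
  a <- ifelse(r > r0, 1L, 0L)
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  n <- nrow(r)
  dens <- sum(a) / 2 / (n * (n - 1L) / 2)
  methods::new("BinaryNetwork", adjacency = a, density = dens)
}

#' Threshold an association matrix across a density grid
#'
#' One [BinaryNetwork] per grid point, all cut from a single edge ranking,
#' so the sweep is exactly nested: the edge set at a smaller density is a
#' subset of the edge set at any larger one.
#'
#' @param m an [AssociationMatrix].
#' @param grid densities from [densityGrid()].
#' @param rankBy see [thresholdByDensity()].
#' @return a list of [BinaryNetwork], one per density, named by density.
#' @export
densitySweep <- function(m, grid = densityGrid(),
                         rankBy = c("signed", "absolute")) {
  r <- assocValues(m)
  n <- nrow(r)
  npair <- n * (n - 1L) / 2
  ord <- edgeOrder(r, rankBy)
  out <- lapply(grid, function(d) {
    K <- roundHalfUp(d * npair)
    if (K == 0L)
      stopf("density %.4g keeps no edges on %d regions (empty network)", d, n)
    methods::new("BinaryNetwork",
                 adjacency = adjacencyFromEdges(ord, K, rownames(r)),
                 density = d)
  })
  names(out) <- formatC(grid, format = "g")
  out
}

# Connectivity check on a 0/1 adjacency matrix (BFS from node 1).
isConnectedAdj <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(TRUE)
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(a[frontier, , drop = FALSE]) > 0)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

largestComponentAdj <- function(a) {
  max(igraph::components(igraph::graph_from_adjacency_matrix(
    a, mode = "undirected"))$csize)
}

#' Smallest sweep density at which neither group's network fragments
#'
#' Walks the grid upward and returns the first density at which both
#' thresholded networks are connected (a single component spanning all
#' regions). This is the effective `Dmin` at which hub analysis and
#' density-matched comparison start.
#'
#' @param mA,mB the two groups' [AssociationMatrix] objects (same regions).
#' @param grid densities from [densityGrid()].
#' @param rankBy see [thresholdByDensity()].
#' @return the minimum unfragmented density (a grid value).
#' @export
minUnfragmentedDensity <- function(mA, mB, grid = densityGrid(),
                                   rankBy = c("signed", "absolute")) {
  if (!identical(rownames(assocValues(mA)), rownames(assocValues(mB))))
    stopf("association matrices must share the same region labels")
  rankBy <- match.arg(rankBy)
  sweepA <- densitySweep(mA, grid, rankBy)
  sweepB <- densitySweep(mB, grid, rankBy)
  for (k in seq_along(grid)) {
    if (isConnectedAdj(adjacency(sweepA[[k]])) &&
        isConnectedAdj(adjacency(sweepB[[k]])))
      return(grid[k])
  }
  last <- length(grid)
  stopf(paste0("networks remain fragmented over the whole grid ",
               "(largest components at density %.3g: %d and %d of %d regions)"),
        grid[last], largestComponentAdj(adjacency(sweepA[[last]])),
        largestComponentAdj(adjacency(sweepB[[last]])),
        nrow(assocValues(mA)))
}

#' @rdname adjacency
#' @export
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)

#' @rdname networkDensity
#' @export
setMethod("networkDensity", "BinaryNetwork", function(x) x@density)

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "BinaryNetwork", function(x) sum(x@adjacency) %/% 2L)

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "BinaryNetwork", function(x) {
  igraph::graph_from_adjacency_matrix(x@adjacency, mode = "undirected")
})

setMethod("show", "BinaryNetwork", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("BinaryNetwork: %d nodes, %d edges (density %.3g)\n",
              n, edgeCount(object), object@density))
})

#' Edge list of a network or association matrix
#'
#' @param x a [BinaryNetwork] or [AssociationMatrix].
#' @return `data.frame` with columns `region_i`, `region_j`, `weight`
#'   (correlation for association matrices, 1 for network edges).
#' @export
edgeList <- function(x) {
  if (methods::is(x, "BinaryNetwork")) {
    a <- adjacency(x)
    w <- NULL
  } else if (methods::is(x, "AssociationMatrix")) {
    a <- assocValues(x)
    w <- a
  } else stopf("edgeList needs a BinaryNetwork or AssociationMatrix")
  up <- upperPairs(nrow(a))
  keep <- if (is.null(w)) a[up$flat] != 0 else rep(TRUE, length(up$flat))
  data.frame(region_i = rownames(a)[up$i[keep]],
             region_j = rownames(a)[up$j[keep]],
             weight = if (is.null(w)) 1 else w[up$flat[keep]],
             stringsAsFactors = FALSE)
}

#' Write a labelled square matrix as TSV
#'
#' Used for association matrices and adjacency matrices; first column holds
#' the region names.
#'
#' @param x an [AssociationMatrix], [BinaryNetwork], or plain matrix.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeMatrixTSV <- function(x, path) {
  m <- if (methods::is(x, "AssociationMatrix")) assocValues(x)
       else if (methods::is(x, "BinaryNetwork")) adjacency(x)
       else as.matrix(x)
  df <- data.frame(region = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (cn in colnames(m))
    df[[cn]] <- if (is.integer(m[, cn])) m[, cn] else fmtNum(m[, cn])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
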