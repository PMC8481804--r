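#' @include covariance.R
NULL

# ---- internal metric cores on igraph objects -------------------------------
# These are shared by the user-facing BinaryNetwork methods and by the
# permutation fast path, which evaluates thousands of graphs per test.

cpLocal <- function(g) {
  v <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(v) <- igraph::V(g)$name
  v
}

lpCore <- function(g) {
  lp <- igraph::mean_distance(g, unconnected = TRUE)
  if (!is.finite(lp))
    stopf("path length undefined: no connected node pairs")
  lp
}

transCore <- function(g) {
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t)) 0 else t
}

# Local efficiency, neighbour-induced-subgraph definition: for each node,
# the global efficiency of the subgraph spanned by its neighbours, with
# distances measured inside that subgraph. (igraph's local_efficiency()
# routes paths outside the neighbourhood, a different variant, so this is
# computed directly on the adjacency via boolean-product BFS.)
elocAdjCore <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[, v] > 0)
    k <- length(nb)
    if (k < 2L) next
    sub <- a[nb, nb, drop = FALSE]
    reach <- sub > 0
    diag(reach) <- TRUE
    d <- matrix(Inf, k, k)
    d[sub > 0] <- 1
    diag(d) <- 0
    step <- 1
    repeat {
      newreach <- (reach %*% sub) > 0 | reach
      step <- step + 1
      fresh <- newreach & !reach
      if (!any(fresh)) break
      d[fresh] <- step
      reach <- newreach
    }
    inv <- 1 / d[row(d) != col(d)]
    inv[!is.finite(inv)] <- 0
    out[v] <- mean(inv)
  }
  out
}

elocVec <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  v <- elocAdjCore(a)
  names(v) <- igraph::V(g)$name
  v
}

btwVec <- function(g) {
  v <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  names(v) <- igraph::V(g)$name
  v
}

# Newman Q of a membership vector on adjacency a.
membershipQ <- function(a, memb) {
  m <- sum(a) / 2
  deg <- rowSums(a)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(a[idx, idx]) / (2 * m) - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# Exact maximum modularity by exhaustive enumeration of set partitions,
# feasible for very small graphs only.
exactModularity <- function(a) {
  n <- nrow(a)
  best <- -Inf
  bestMemb <- integer(n)
  memb <- integer(n)
  recurse <- function(i, nBlocks) {
    if (i > n) {
      q <- membershipQ(a, memb)
      if (q > best) {
        best <<- q
        bestMemb <<- memb
      }
      return(invisible())
    }
    for (b in seq_len(nBlocks + 1L)) {
      memb[i] <<- b
      recurse(i + 1L, max(nBlocks, b))
    }
  }
  recurse(1L, 0L)
  list(q = best, memb = bestMemb)
}

# Local polish of a partition: greedy single-node moves and pairwise
# community merges to a local optimum. Delta-Q is computed from per-pass
# community aggregates (E = A %*% indicator, sigma = community degrees), so
# a full pass is cheap even at atlas scale.
refineMembership <- function(a, memb) {
  m <- sum(a) / 2
  deg <- rowSums(a)
  n <- nrow(a)
  repeat {
    improved <- FALSE
    comms <- sort(unique(memb))
    cid <- match(memb, comms)
    C <- length(comms)
    M <- matrix(0, n, C)
    M[cbind(seq_len(n), cid)] <- 1
    E <- a %*% M
    sigma <- as.numeric(crossprod(deg, M))
    for (i in seq_len(n)) {
      ci <- cid[i]
      gains <- (E[i, ] - E[i, ci]) / m -
        deg[i] * (sigma - (sigma[ci] - deg[i])) / (2 * m^2)
      gains[ci] <- 0
      d <- which.max(gains)
      if (gains[d] > 1e-12) {
        cid[i] <- d
        E[, ci] <- E[, ci] - a[, i]
        E[, d] <- E[, d] + a[, i]
        sigma[ci] <- sigma[ci] - deg[i]
        sigma[d] <- sigma[d] + deg[i]
        improved <- TRUE
      }
    }
    alive <- sort(unique(cid))
    if (length(alive) > 1L) {
      M2 <- matrix(0, n, length(alive))
      M2[cbind(seq_len(n), match(cid, alive))] <- 1
      Ecc <- crossprod(M2, a %*% M2)
      sig2 <- as.numeric(crossprod(deg, M2))
      gains <- Ecc / m - outer(sig2, sig2) / (2 * m^2)
      diag(gains) <- 0
      wm <- which(gains == max(gains), arr.ind = TRUE)[1L, ]
      if (gains[wm[1L], wm[2L]] > 1e-12) {
        cid[cid == alive[wm[1L]]] <- alive[wm[2L]]
        improved <- TRUE
      }
    }
    memb <- cid
    if (!improved) break
  }
  memb
}

modCore <- function(g, seed, restarts = 10L, exactMax = 8L) {
  if (igraph::ecount(g) == 0L)
    stopf("modularity undefined on an edgeless network")
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  if (nrow(a) <= exactMax) {
    res <- exactModularity(a)
    best <- res$memb
    bestQ <- res$q
  } else {
    best <- NULL
    bestQ <- -Inf
    for (k in seq_len(restarts)) {
      set.seed(as.integer(seed) + k - 1L)
      memb <- as.integer(igraph::membership(igraph::cluster_louvain(g)))
      q <- membershipQ(a, memb)
      if (q > bestQ) {
        bestQ <- q
        best <- memb
      }
    }
    best <- refineMembership(a, best)
    bestQ <- membershipQ(a, best)
  }
  part <- match(best, unique(best))
  names(part) <- igraph::V(g)$name
  list(q = bestQ, partition = part)
}

rewireCore <- function(g, seed, swapsPerEdge = 10L, maxRetries = 50L) {
  if (igraph::ecount(g) < 2L)
    stopf("rewiring needs at least 2 edges")
  wantConnected <- igraph::is_connected(g)
  niter <- as.integer(swapsPerEdge) * igraph::ecount(g)
  for (try in seq_len(maxRetries)) {
    set.seed(as.integer(seed) + try - 1L)
    r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                  niter = niter))
    if (!wantConnected || igraph::is_connected(r)) return(r)
  }
  stopf("degree-preserving rewiring failed to produce a connected graph in %d attempts",
        maxRetries)
}

swiCore <- function(g, nRandom, seed, swapsPerEdge = 10L) {
  cp <- mean(cpLocal(g))
  lp <- lpCore(g)
  subseeds <- deriveSeeds(seed, nRandom)
  rcp <- numeric(nRandom)
  rlp <- numeric(nRandom)
  for (k in seq_len(nRandom)) {
    r <- rewireCore(g, subseeds[k], swapsPerEdge)
    rcp[k] <- mean(cpLocal(r))
    rlp[k] <- lpCore(r)
  }
  if (mean(rcp) == 0 || mean(rlp) == 0)
    stopf("small-world indices undefined: rewired ensemble has zero mean clustering or path length")
  gamma <- cp / mean(rcp)
  lambda <- lp / mean(rlp)
  c(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

# ---- user-facing metric surface --------------------------------------------

#' Degree of every region
#'
#' @param net a [BinaryNetwork].
#' @return named integer vector; sums to twice the edge count.
#' @export
degreeSequence <- function(net) {
  k <- rowSums(adjacency(net))
  storage.mode(k) <- "integer"
  k
}

#' Clustering coefficient of every region
#'
#' For node \eqn{i} with degree \eqn{k_i}, the fraction of the
#' \eqn{k_i(k_i-1)/2} possible edges among its neighbours that exist; 0 when
#' \eqn{k_i < 2}. The network-level value (`Cp`) is the mean over nodes.
#'
#' @param net a [BinaryNetwork].
#' @return named numeric vector in `[0, 1]`.
#' @export
clusteringCoefficients <- function(net) cpLocal(asIgraph(net))

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs. On a fragmented
#' network unreachable pairs are excluded from the average and their count
#' is reported via `message()`; the density sweep normally starts at a
#' connectivity-checked `Dmin`, so this is a safeguard.
#'
#' @param net a [BinaryNetwork].
#' @return a single number (`>= 1`).
#' @export
pathLength <- function(net) {
  g <- asIgraph(net)
  d <- igraph::distances(g)
  off <- d[upper.tri(d)]
  nInf <- sum(is.infinite(off))
  if (nInf == length(off))
    stopf("path length undefined: no connected node pairs")
  if (nInf > 0)
    message(sprintf("pathLength: %d unreachable node pair(s) excluded", nInf))
  mean(off[is.finite(off)])
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over node pairs, with unreachable
#' pairs contributing zero; the inverse of the harmonic mean distance.
#'
#' @param net a [BinaryNetwork].
#' @return a number in `[0, 1]`.
#' @export
globalEfficiency <- function(net) {
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0L) return(0)
  igraph::global_efficiency(g)
}

#' Local efficiency of every region
#'
#' Global efficiency of the subgraph induced by each node's neighbours
#' (0 for nodes with fewer than 2 neighbours): how fault-tolerant
#' communication around a node is if the node is removed.
#'
#' @param net a [BinaryNetwork].
#' @return named numeric vector in `[0, 1]`.
#' @export
localEfficiency <- function(net) elocVec(asIgraph(net))

#' Transitivity (whole-graph clustering)
#'
#' Three times the number of triangles over the number of connected triples;
#' 0 when the graph has no connected triple.
#'
#' @param net a [BinaryNetwork].
#' @return a number in `[0, 1]`.
#' @export
networkTransitivity <- function(net) transCore(asIgraph(net))

#' Newman modularity of the best partition found
#'
#' Exact Q-maximization is NP-hard. Very small graphs (up to `exactMax`
#' nodes) are solved exactly by exhaustive enumeration of set partitions;
#' larger graphs use a seeded multi-restart agglomerative (Louvain) search
#' whose best partition is polished by greedy single-node moves and
#' community merges to a local optimum. Identical seeds give identical
#' partitions.
#'
#' @param net a [BinaryNetwork] with at least one edge.
#' @param seed integer seed (used by the restart search).
#' @param restarts number of seeded restarts.
#' @param exactMax largest node count solved exactly.
#' @return `list(q = , partition = )` with a named integer community id per
#'   region.
#' @export
networkModularity <- function(net, seed = 1L, restarts = 10L,
                              exactMax = 8L) {
  modCore(asIgraph(net), seed, restarts, exactMax)
}

#' Betweenness centrality of every region
#'
#' Brandes' accumulation: for every unordered pair of distinct nodes, each
#' intermediate node on their shortest paths is credited the fraction of
#' those paths passing through it (endpoints excluded). Values are raw
#' (unnormalized); the hub z-rule and permutation group differences are
#' invariant to positive rescaling.
#'
#' @param net a [BinaryNetwork].
#' @return named nonnegative numeric vector.
#' @export
betweennessCentrality <- function(net) btwVec(asIgraph(net))

#' Degree-preserving rewiring (Maslov-Sneppen null model)
#'
#' Randomizes edges by repeated double-edge swaps, preserving every node's
#' degree and keeping the graph simple. If the input is connected the
#' rewired graph is re-checked and rewiring is retried (fresh subseed) until
#' connectedness is recovered, up to `maxRetries`.
#'
#' @param net a [BinaryNetwork] with at least 2 edges.
#' @param seed integer seed.
#' @param swapsPerEdge attempted swaps per edge.
#' @param maxRetries connectivity retry budget.
#' @return a rewired [BinaryNetwork] at the same density.
#' @export
rewireDegreePreserving <- function(net, seed = 1L, swapsPerEdge = 10L,
                                   maxRetries = 50L) {
  g <- rewireCore(asIgraph(net), seed, swapsPerEdge, maxRetries)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  storage.mode(a) <- "integer"
  dimnames(a) <- dimnames(adjacency(net))
  methods::new("BinaryNetwork", adjacency = a, density = networkDensity(net))
}

#' Small-world indices against a rewired null ensemble
#'
#' `gamma` is the network's mean clustering divided by the mean clustering
#' of `nRandom` degree-preserving rewired graphs, `lambda` the analogous
#' path-length ratio, and `sigma = gamma / lambda` the small-world index
#' (clearly above 1 for small-world topology).
#'
#' @param net a [BinaryNetwork] (connected, for well-defined path lengths).
#' @param nRandom size of the null ensemble.
#' @param seed integer seed; each replicate gets a derived subseed.
#' @param swapsPerEdge rewiring intensity, see [rewireDegreePreserving()].
#' @return named numeric vector `c(gamma, lambda, sigma)`.
#' @export
smallWorldIndices <- function(net, nRandom = 20L, seed = 1L,
                              swapsPerEdge = 10L) {
  if (nRandom < 1L) stopf("nRandom must be at least 1")
  swiCore(asIgraph(net), nRandom, seed, swapsPerEdge)
}

#' Normalize nodal values by the network mean
#'
#' The convention for "normalized" regional measures: each node's value
#' divided by the mean over nodes, so the output has mean 1. Any affine
#' within-network rescaling cancels in between-group comparisons under this
#' convention.
#'
#' @param values numeric vector of per-node values with nonzero mean.
#' @return numeric vector with mean 1.
#' @export
normalizeNodal <- function(values) {
  m <- mean(values)
  if (m == 0) stopf("cannot normalize: nodal values have zero mean")
  values / m
}

#' All nine global metrics of a binary network
#'
#' Mean clustering (`Cp`), characteristic path length (`Lp`), global
#' efficiency (`Eglob`), mean local efficiency (`Eloc`), transitivity (`T`),
#' modularity (`Q`), and the rewired-null normalized `gamma`, `lambda`,
#' `sigma`.
#'
#' @param net a [BinaryNetwork].
#' @param nRandom rewired ensemble size for `gamma`/`lambda`/`sigma`.
#' @param seed integer seed (modularity restarts and rewiring).
#' @param swapsPerEdge rewiring intensity.
#' @return named numeric vector of the nine values.
#' @examples
#' m <- associationMatrix(generateCohort(
#'   nullConfig(builtinAtlas("desikan_killiany_68"), seed = 3))[
#'     , 1:23])
#' globalMetrics(thresholdByDensity(m, 0.2), nRandom = 5)
#' @export
globalMetrics <- function(net, nRandom = 20L, seed = 1L, swapsPerEdge = 10L) {
  g <- asIgraph(net)
  swi <- swiCore(g, nRandom, seed, swapsPerEdge)
  c(clustering = mean(cpLocal(g)),
    path_length = lpCore(g),
    global_efficiency = igraph::global_efficiency(g),
    local_efficiency = mean(elocVec(g)),
    transitivity = transCore(g),
    modularity = modCore(g, seed)$q,
    swi)
}
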