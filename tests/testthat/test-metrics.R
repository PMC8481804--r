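test_that("worked small-graph examples give the textbook values", {
  k3 <- adjToNet(completeAdj(3))
  expect_equal(unname(degreeSequence(k3)), c(2L, 2L, 2L))
  expect_equal(unname(clusteringCoefficients(k3)), rep(1, 3))
  expect_equal(pathLength(k3), 1)
  expect_equal(globalEfficiency(k3), 1)
  expect_equal(networkTransitivity(k3), 1)

  path3 <- adjToNet(pathGraphAdj())
  expect_equal(unname(clusteringCoefficients(path3)), rep(0, 3))
  expect_equal(pathLength(path3), 4 / 3)
  expect_equal(globalEfficiency(path3), 5 / 6)
  expect_equal(unname(betweennessCentrality(path3)), c(0, 1, 0))

  star <- adjToNet(starAdj(3))
  expect_equal(unname(degreeSequence(star)), c(3L, 1L, 1L, 1L))
  expect_equal(pathLength(star), 1.5)
  expect_equal(unname(localEfficiency(star)), rep(0, 4))
  expect_equal(networkTransitivity(star), 0)

  paw <- adjToNet(pawGraphAdj())
  expect_equal(unname(clusteringCoefficients(paw)), c(1, 1, 1 / 3, 0))
  expect_equal(mean(clusteringCoefficients(paw)), 7 / 12)
  expect_equal(networkTransitivity(paw), 3 / 5)
  expect_equal(unname(localEfficiency(paw))[3], 1 / 3)

  k4 <- adjToNet(completeAdj(4))
  expect_equal(unname(betweennessCentrality(k4)), rep(0, 4))
  expect_equal(unname(localEfficiency(k4)), rep(1, 4))

  ds <- adjToNet(doubleStarAdj(5))
  b <- betweennessCentrality(ds)
  expect_equal(unname(b[1:2]), c(40, 40))
  expect_equal(unname(b[3:12]), rep(0, 10))

  expect_equal(globalEfficiency(adjToNet(rbind(c(0L, 0L), c(0L, 0L)))), 0)
})

test_that("every metric matches its brute-force oracle on random graphs", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:8, 1)
    a <- randomAdj(n, runif(1, 0.25, 0.6), 400 + s)
    net <- adjToNet(a)
    expect_equal(unname(degreeSequence(net)), rowSums(a), ignore_attr = TRUE)
    expect_equal(sum(degreeSequence(net)), 2L * edgeCount(net))
    expect_equal(unname(clusteringCoefficients(net)), oracleClustering(a))
    expect_equal(globalEfficiency(net), oracleGlobalEfficiency(a))
    expect_equal(unname(localEfficiency(net)), oracleLocalEfficiency(a))
    expect_equal(networkTransitivity(net), oracleTransitivity(a))
    expect_equal(unname(betweennessCentrality(net)),
                 unname(oracleBetweenness(a)))
    lp <- tryCatch(suppressMessages(pathLength(net)),
                   error = function(e) NULL)
    if (!is.null(lp)) expect_equal(lp, oraclePathLength(a))
    expect_equal(networkModularity(net, seed = s)$q, oracleMaxModularity(a))
  }
})

test_that("modularity handles the canonical cases and is seed-stable", {
  twoK3 <- matrix(0L, 6, 6, dimnames = rep(list(LETTERS[1:6]), 2))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6),
                 c(1, 4)))
    twoK3[e[1], e[2]] <- twoK3[e[2], e[1]] <- 1L
  res <- networkModularity(adjToNet(twoK3), seed = 1)
  expect_equal(res$q, 5 / 14)
  expect_equal(unname(res$partition[1:3]), rep(res$partition[["A"]], 3))
  expect_equal(unname(res$partition[4:6]), rep(res$partition[["D"]], 3))
  expect_false(res$partition[["A"]] == res$partition[["D"]])

  expect_equal(networkModularity(adjToNet(completeAdj(5)), seed = 1)$q, 0)
  expect_error(networkModularity(adjToNet(matrix(0L, 3, 3))), "edgeless")

  # large-graph search path: deterministic under a fixed seed
  a <- randomAdj(40, 0.15, 77)
  r1 <- networkModularity(adjToNet(a), seed = 9)
  r2 <- networkModularity(adjToNet(a), seed = 9)
  expect_identical(r1, r2)
  # and never below a single plain Louvain run
  g <- asIgraph(adjToNet(a))
  set.seed(9)
  expect_gte(r1$q, igraph::modularity(igraph::cluster_louvain(g)) - 1e-12)
})

test_that("rewiring preserves the degree multiset and determinism", {
  for (s in 1:20) {
    a <- randomAdj(14, 0.3, 500 + s)
    net <- adjToNet(a)
    rw <- rewireDegreePreserving(net, seed = s)
    expect_equal(sort(degreeSequence(rw)), sort(degreeSequence(net)))
    expect_equal(networkDensity(rw), networkDensity(net))
    expect_true(all(diag(adjacency(rw)) == 0L))
  }
  net <- adjToNet(randomAdj(14, 0.3, 550))
  expect_identical(adjacency(rewireDegreePreserving(net, seed = 4)),
                   adjacency(rewireDegreePreserving(net, seed = 4)))
  # K3 admits no valid swap
  k3 <- adjToNet(completeAdj(3))
  expect_identical(adjacency(rewireDegreePreserving(k3, seed = 1)),
                   adjacency(k3))
  # connected input stays connected
  ring <- igraph::as_adjacency_matrix(
    igraph::make_ring(20), sparse = FALSE)
  rw <- rewireDegreePreserving(adjToNet(ring), seed = 2)
  expect_true(igraph::is_connected(asIgraph(rw)))
})

test_that("small-world indices separate lattices from random graphs", {
  # ring lattice with sparse shortcuts: strongly small-world
  set.seed(1)
  g <- igraph::sample_smallworld(1, 60, 3, 0.05)
  g <- igraph::simplify(g)
  lattice <- adjToNet(igraph::as_adjacency_matrix(g, sparse = FALSE))
  swi <- smallWorldIndices(lattice, nRandom = 8, seed = 3)
  expect_gt(swi[["gamma"]], 1.5)
  expect_gt(swi[["sigma"]], 1.2)
  expect_equal(swi[["sigma"]], swi[["gamma"]] / swi[["lambda"]])

  # Erdos-Renyi: sigma near 1
  set.seed(2)
  ge <- igraph::sample_gnp(60, 0.15)
  while (!igraph::is_connected(ge)) ge <- igraph::sample_gnp(60, 0.15)
  er <- adjToNet(igraph::as_adjacency_matrix(ge, sparse = FALSE))
  swiER <- smallWorldIndices(er, nRandom = 8, seed = 3)
  expect_lt(abs(swiER[["sigma"]] - 1), 0.25)
})

test_that("nodal normalization divides by the mean", {
  expect_equal(normalizeNodal(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(normalizeNodal(rep(3.7, 5)), rep(1, 5))
  set.seed(3)
  v <- rexp(50)
  expect_equal(mean(normalizeNodal(v)), 1, tolerance = 1e-12)
  expect_error(normalizeNodal(c(-1, 1)), "zero mean")
})

test_that("adding an edge never decreases Eglob and never increases Lp", {
  for (s in 1:15) {
    a <- randomAdj(10, 0.35, 600 + s)
    if (!igraph::is_connected(asIgraph(adjToNet(a)))) next
    absent <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    set.seed(s)
    pick <- absent[sample(nrow(absent), 1), ]
    a2 <- a
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 1L
    expect_gte(globalEfficiency(adjToNet(a2)),
               globalEfficiency(adjToNet(a)) - 1e-12)
    expect_lte(pathLength(adjToNet(a2)), pathLength(adjToNet(a)) + 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  a <- randomAdj(12, 0.35, 700)
  set.seed(7)
  perm <- sample(12)
  b <- a[perm, perm]
  expect_equal(unname(clusteringCoefficients(adjToNet(a)))[perm],
               unname(clusteringCoefficients(adjToNet(b))))
  expect_equal(unname(betweennessCentrality(adjToNet(a)))[perm],
               unname(betweennessCentrality(adjToNet(b))))
  expect_equal(globalEfficiency(adjToNet(a)), globalEfficiency(adjToNet(b)))
  expect_equal(networkTransitivity(adjToNet(a)),
               networkTransitivity(adjToNet(b)))
})
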