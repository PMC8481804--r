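test_that("age residualization removes the age effect exactly", {
  atl <- toyAtlas(2)
  age <- c(20, 30, 40, 50, 60)
  # thickness exactly linear in age -> all residuals zero
  x <- outer(rep(1, 5), c(3, 2.8, 2.6, 2.4)) + outer(age, c(-.01, .02, 0, .005))
  colnames(x) <- regionColumns(atl)
  te <- ThicknessExperiment(x, rep("g", 5), age, atl,
                            subjectIds = paste0("s", 1:5))
  res <- thicknessValues(residualizeAge(te))
  expect_equal(max(abs(res)), 0, tolerance = 1e-12)

  # random table: residuals orthogonal to age and mean-zero
  te2 <- toyThickness(nSubjects = 10, seed = 4)
  res2 <- thicknessValues(residualizeAge(te2))
  expect_lt(max(abs(colMeans(res2))), 1e-10)
  expect_lt(max(abs(crossprod(res2, subjectAges(te2))))
            , 1e-8)

  # constant age: mean-centring with a warning
  te3 <- ThicknessExperiment(x, rep("g", 5), rep(40, 5), atl,
                             subjectIds = paste0("s", 1:5))
  expect_warning(r3 <- residualizeAge(te3), "constant")
  expect_equal(thicknessValues(r3), scale(x, scale = FALSE),
               ignore_attr = TRUE)

  expect_error(residualizeAge(te2[, 1:2]), "3 subjects")
})

test_that("association matrix equals the textbook Pearson computation", {
  atl <- toyAtlas(2)
  set.seed(8)
  vals <- matrix(rnorm(24), 6, 4)
  te <- residualTable(vals, atl)
  m <- associationMatrix(te)
  r <- assocValues(m)
  # direct covariance / sigma oracle
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    ci <- vals[, i] - mean(vals[, i]); cj <- vals[, j] - mean(vals[, j])
    oracle[i, j] <- sum(ci * cj) / sqrt(sum(ci^2) * sum(cj^2))
  }
  diag(oracle) <- 0
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  expect_identical(r, t(r))
  expect_equal(diag(r), setNames(rep(0, 4), colnames(r)))
})

test_that("perfect and anti-correlated regions give r = +/- 1", {
  atl <- toyAtlas(2)
  set.seed(9)
  base <- rnorm(8)
  vals <- cbind(base, base, -base, rnorm(8))
  te <- residualTable(vals, atl)
  r <- assocValues(associationMatrix(te))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)

  vals2 <- cbind(base, rep(0, 8), rnorm(8), rnorm(8))
  expect_error(associationMatrix(residualTable(vals2, atl)), "lh_r2")
})

test_that("association matrix preconditions are enforced", {
  te <- toyThickness(nSubjects = 6)  # two groups present
  expect_error(associationMatrix(te), "single group")
  one <- te[, groupLabels(te) == "g1"]
  expect_error(associationMatrix(one), "4 subjects")
})

test_that("association matrix is invariant to subject and region order", {
  atl <- toyAtlas(3)
  te <- toyThickness(nSubjects = 8, atlas = atl, seed = 2,
                     group = rep("g", 8))
  r <- assocValues(associationMatrix(te))
  # subject reordering
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  te2 <- ThicknessExperiment(thicknessValues(te)[perm, ],
                             groupLabels(te)[perm], subjectAges(te)[perm],
                             atl, subjectIds = paste0("s", 1:8))
  expect_equal(assocValues(associationMatrix(te2)), r, tolerance = 1e-12)
  # region permutation via a permuted atlas
  rperm <- sample(6)
  atl2 <- BrainAtlas("perm", atl@regions$label[rperm],
                     atl@regions$hemisphere[rperm])
  te3 <- ThicknessExperiment(thicknessValues(te)[, rperm],
                             groupLabels(te), subjectAges(te), atl2,
                             subjectIds = paste0("s", 1:8))
  expect_equal(unname(assocValues(associationMatrix(te3))),
               unname(r[rperm, rperm]), tolerance = 1e-12)
})

test_that("density thresholding keeps exactly the top-K edges", {
  m <- workedAssoc()  # AB .9, AC .8, AD .7, BC .5, BD .3, CD .1
  labs <- rownames(assocValues(m))
  net <- thresholdByDensity(m, 0.5)  # K = 3 of 6: the star on A
  expect_equal(edgeCount(net), 3L)
  a <- adjacency(net)
  expect_equal(unname(a[labs[1], ]), c(0L, 1L, 1L, 1L))
  expect_equal(sum(a[labs[2:4], labs[2:4]]), 0L)

  full <- thresholdByDensity(m, 1.0)
  expect_equal(edgeCount(full), 6L)
  expect_error(thresholdByDensity(m, 0.01), "empty network")
  expect_error(thresholdByDensity(m, 1.2), "density")
})

test_that("ties at the density cut break to the lexicographically smaller pair", {
  atl <- toyAtlas(2)
  r <- matrix(0, 4, 4, dimnames = list(regionColumns(atl),
                                       regionColumns(atl)))
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.5   # tied at the cut
  r[2, 4] <- r[4, 2] <- 0.5   # tied at the cut
  r[3, 4] <- r[4, 3] <- 0.1
  m <- new("AssociationMatrix", r = r, group = "g", nSubjects = 5L)
  net <- thresholdByDensity(m, 2 / 6)  # K = 2
  expect_equal(edgeCount(net), 2L)
  expect_equal(adjacency(net)[1, 3], 1L)  # (1,3) beats (2,4)
  expect_equal(adjacency(net)[2, 4], 0L)
})

test_that("absolute thresholding uses a strict inequality", {
  m <- workedAssoc()
  net <- thresholdAbsolute(m, 0.1)
  expect_equal(edgeCount(net), 5L)        # CD at 0.1 is excluded
  expect_equal(adjacency(net)[3, 4], 0L)
  expect_equal(networkDensity(net), 5 / 6)

  expect_equal(edgeCount(thresholdAbsolute(m, 0.95)), 0L)
  expect_equal(networkDensity(thresholdAbsolute(m, 0.95)), 0)

  rneg <- -assocValues(m)
  mneg <- new("AssociationMatrix", r = rneg, group = "g", nSubjects = 5L)
  expect_equal(edgeCount(thresholdAbsolute(mneg, 0)), 0L)
})

test_that("the density sweep is nested and consistent with absolute cuts", {
  expect_length(densityGrid(), 21L)
  expect_error(densityGrid(0.5, 0.5), "dMin")

  for (s in 1:20) {
    m <- randomAssoc(12, seed = 300 + s)
    nets <- densitySweep(m, densityGrid(0.1, 0.5, 0.1))
    for (k in 2:length(nets))
      expect_true(all(adjacency(nets[[k - 1]]) <= adjacency(nets[[k]])))
    # cross-operation consistency: absolute cut just below the K-th value
    vals <- sort(assocValues(m)[upper.tri(assocValues(m))],
                 decreasing = TRUE)
    K <- edgeCount(nets[[2]])
    netAbs <- thresholdAbsolute(m, vals[K] - 1e-9)
    expect_identical(adjacency(netAbs), adjacency(nets[[2]]))
  }
})

test_that("minimum unfragmented density finds the first connected grid point", {
  # matrices whose top n-1 entries form a star (spanning tree) on node 1
  atl <- toyAtlas(5)
  labs <- regionColumns(atl)
  r <- matrix(0, 10, 10, dimnames = list(labs, labs))
  r[1, 2:10] <- r[2:10, 1] <- seq(0.9, 0.82, length.out = 9)
  other <- upper.tri(r) & r == 0
  r[other] <- seq(0.5, 0.1, length.out = sum(other))
  r <- pmax(r, t(r))
  diag(r) <- 0
  m <- new("AssociationMatrix", r = r, group = "g", nSubjects = 6L)
  # (n-1)/(n(n-1)/2) = 0.2; first grid point >= 0.2 holds all 9 star edges
  expect_equal(minUnfragmentedDensity(m, m, densityGrid(0.1, 0.5, 0.02)),
               0.2)

  # two uncorrelated blocks cannot connect at low density
  r2 <- matrix(0, 10, 10, dimnames = list(labs, labs))
  r2[1:5, 1:5] <- 0.8
  r2[6:10, 6:10] <- 0.8
  diag(r2) <- 0
  m2 <- new("AssociationMatrix", r = r2, group = "g", nSubjects = 6L)
  expect_error(minUnfragmentedDensity(m2, m2, densityGrid(0.05, 0.1, 0.05)),
               "fragmented")
})

test_that("edge lists and matrix TSV export round-trip the adjacency", {
  m <- workedAssoc()
  el <- edgeList(m)
  expect_equal(nrow(el), 6L)
  expect_equal(sort(el$weight), sort(c(.9, .8, .7, .5, .3, .1)))
  net <- thresholdByDensity(m, 0.5)
  expect_equal(nrow(edgeList(net)), 3L)

  path <- tempfile(fileext = ".tsv")
  writeMatrixTSV(m, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), assocValues(m), ignore_attr = TRUE)
})
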