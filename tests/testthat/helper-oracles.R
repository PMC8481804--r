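# Independent brute-force oracles for graph metrics. Everything here is
# deliberately naive (triple loops, exhaustive enumeration) and shares no
# code with the package implementation.

# Seeded Erdos-Renyi adjacency matrix with at least one edge.
randomAdj <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    if (sum(a) > 0) break
  }
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  a
}

adjToNet <- function(a) {
  n <- nrow(a)
  if (is.null(dimnames(a)))
    dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  storage.mode(a) <- "integer"
  new("BinaryNetwork", adjacency = a, density = sum(a) / 2 / (n * (n - 1) / 2))
}

# Named small graphs used in worked examples.
pathGraphAdj <- function() {       # A-B-C
  a <- matrix(0L, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  a["A", "B"] <- a["B", "A"] <- a["B", "C"] <- a["C", "B"] <- 1L
  a
}
pawGraphAdj <- function() {        # triangle ABC + pendant D on C
  a <- matrix(0L, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1L
  a
}
completeAdj <- function(n) {
  a <- matrix(1L, n, n) - diag(1L, n)
  dimnames(a) <- rep(list(paste0("n", 1:n)), 2)
  a
}
starAdj <- function(nLeaves) {     # center = node 1
  n <- nLeaves + 1
  a <- matrix(0L, n, n, dimnames = rep(list(paste0("n", 1:n)), 2))
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}
doubleStarAdj <- function(leavesEach = 5) {  # two joined centers
  n <- 2 + 2 * leavesEach
  a <- matrix(0L, n, n, dimnames = rep(list(paste0("n", 1:n)), 2))
  a[1, 2] <- a[2, 1] <- 1L
  for (k in seq_len(leavesEach)) {
    a[1, 2 + k] <- a[2 + k, 1] <- 1L
    a[2, 2 + leavesEach + k] <- a[2 + leavesEach + k, 2] <- 1L
  }
  a
}

oracleFloydWarshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oraclePathLength <- function(a) {
  d <- oracleFloydWarshall(a)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

oracleGlobalEfficiency <- function(a) {
  d <- oracleFloydWarshall(a)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracleClustering <- function(a) {
  n <- nrow(a)
  sapply(1:n, function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  })
}

oracleLocalEfficiency <- function(a) {
  n <- nrow(a)
  sapply(1:n, function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracleGlobalEfficiency(a[nb, nb, drop = FALSE])
  })
}

oracleTransitivity <- function(a) {
  n <- nrow(a)
  triangles <- 0
  triples <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i == j || j == k || i == k) next
    if (a[i, j] && a[j, k]) {
      triples <- triples + 1            # ordered connected triple through j
      if (a[i, k]) triangles <- triangles + 1
    }
  }
  if (triples == 0) return(0)
  triangles / triples                    # = 3*tri / triples in unordered form
}

# Betweenness by exhaustive shortest-path enumeration (n <= 8): for each
# unordered pair, enumerate every simple path, keep the shortest, and credit
# each interior node its fraction.
oracleBetweenness <- function(a) {
  n <- nrow(a)
  btw <- numeric(n)
  allPaths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in which(a[v, ] > 0)) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- allPaths(s, t)
    if (!length(paths)) next
    lens <- sapply(paths, length)
    sp <- paths[lens == min(lens)]
    for (p in sp) {
      interior <- p[-c(1, length(p))]
      btw[interior] <- btw[interior] + 1 / length(sp)
    }
  }
  names(btw) <- rownames(a)
  btw
}

# Newman modularity of a given membership vector.
oracleQ <- function(a, memb) {
  m <- sum(a) / 2
  deg <- rowSums(a)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(a[idx, idx]) / (2 * m) - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# Maximum modularity by exhaustive search over all set partitions (n <= 8).
oracleMaxModularity <- function(a) {
  n <- nrow(a)
  best <- -Inf
  memb <- integer(n)
  recurse <- function(i, nBlocks) {
    if (i > n) {
      q <- oracleQ(a, memb[1:n])
      if (q > best) best <<- q
      return()
    }
    for (b in 1:(nBlocks + 1)) {
      memb[i] <<- b
      recurse(i + 1, max(nBlocks, b))
    }
  }
  recurse(1L, 0L)
  best
}

# Independent trapezoid: explicit interval sum, no shared code with pracma.
oracleTrapz <- function(x, y) {
  s <- 0
  for (k in seq_len(length(x) - 1))
    s <- s + (x[k + 1] - x[k]) * (y[k] + y[k + 1]) / 2
  s
}
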