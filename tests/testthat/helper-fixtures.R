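# Small in-code fixtures for the I/O and covariance tests.

toyAtlas <- function(nPerHemi = 2) {
  BrainAtlas(sprintf("toy_%d", 2 * nPerHemi),
             rep(paste0("r", seq_len(nPerHemi)), 2),
             rep(c("left", "right"), each = nPerHemi))
}

# A well-formed subjects x regions table on a toy atlas.
toyThickness <- function(nSubjects = 6, atlas = toyAtlas(), seed = 1,
                         group = rep_len(c("g1", "g2"), nSubjects),
                         age = seq(25, 55, length.out = nSubjects)) {
  set.seed(seed)
  x <- matrix(2.5 + rnorm(nSubjects * nRegions(atlas), sd = 0.2),
              nSubjects, nRegions(atlas),
              dimnames = list(sprintf("s%02d", seq_len(nSubjects)),
                              regionColumns(atlas)))
  ThicknessExperiment(x, group, age, atlas)
}

# ThicknessExperiment carrying pre-computed residual values (skips the
# positivity screen), for direct correlation tests.
residualTable <- function(values, atlas, group = "g1",
                          age = seq_len(nrow(values))) {
  colnames(values) <- regionColumns(atlas)
  rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  ThicknessExperiment(values, rep(group, nrow(values)), age, atlas,
                      residualized = TRUE)
}

# The 4-region worked association matrix: upper triangle
# AB .9, AC .8, AD .7, BC .5, BD .3, CD .1 (regions renamed to atlas cols).
workedAssoc <- function() {
  atl <- toyAtlas(2)
  r <- matrix(0, 4, 4, dimnames = list(regionColumns(atl),
                                       regionColumns(atl)))
  vals <- c(.9, .8, .7, .5, .3, .1)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    r[pairs[k, 1], pairs[k, 2]] <- vals[k]
    r[pairs[k, 2], pairs[k, 1]] <- vals[k]
  }
  new("AssociationMatrix", r = r, group = "g1", nSubjects = 6L)
}

# Symmetric random "correlation-like" matrix with zero diagonal.
randomAssoc <- function(n, seed) {
  set.seed(seed)
  r <- matrix(runif(n * n, -1, 1), n)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  labs <- paste0("R", seq_len(n))
  dimnames(r) <- list(labs, labs)
  new("AssociationMatrix", r = r, group = "g", nSubjects = 10L)
}
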