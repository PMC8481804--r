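#' @include io.R
NULL

#' Full control over the cohort generative model
#'
#' See [CohortConfig] for the data model. Most users want the canned
#' configurations [nullConfig()] (no group difference), [effectConfig()]
#' (group contrast in covariance structure) and [hubConfig()] (planted
#' connector hub); this constructor exposes every knob.
#'
#' @param atlas a [BrainAtlas].
#' @param loadingsA,loadingsB regions-by-factors loading matrices (mm).
#' @param regionMeans per-region mean thickness, mm (recycled).
#' @param ageSlopes per-region thickness change per year of age, mm/year
#'   (recycled; cortical thinning makes these small and negative).
#' @param nPerGroup subjects per group.
#' @param ageMean,ageSd,ageRange age distribution in years: Gaussian
#'   truncated to `ageRange`.
#' @param noiseSd independent residual noise, mm.
#' @param seed master seed.
#' @return a [CohortConfig].
#' @export
cohortConfig <- function(atlas, loadingsA, loadingsB = loadingsA,
                         regionMeans = 2.5, ageSlopes = -0.005,
                         nPerGroup = 23L, ageMean = 39.5, ageSd = 9,
                         ageRange = c(18, 60), noiseSd = 0.10, seed = 1L) {
  n <- nRegions(atlas)
  cfg <- methods::new("CohortConfig",
    nPerGroup = as.integer(nPerGroup), atlas = atlas,
    nFactors = as.integer(ncol(loadingsA)),
    loadingsA = loadingsA, loadingsB = loadingsB,
    regionMeans = rep_len(regionMeans, n), ageMean = ageMean, ageSd = ageSd,
    ageRange = as.numeric(ageRange), ageSlopes = rep_len(ageSlopes, n),
    noiseSd = noiseSd, seed = as.integer(seed))
  methods::validObject(cfg)
  cfg
}

# Homotopic community assignment: regions are cut into nCommunities
# contiguous blocks per hemisphere, with left/right counterparts sharing a
# block, echoing the strong homotopic covariance seen in real SCN matrices.
homotopicCommunities <- function(atlas, nCommunities) {
  hemi <- hemispheres(atlas)
  comm <- integer(nRegions(atlas))
  for (h in c("left", "right")) {
    idx <- which(hemi == h)
    comm[idx] <- as.integer(cut(seq_along(idx), nCommunities, labels = FALSE))
  }
  comm
}

# Deterministic mild regional variation so region means are not all equal.
defaultRegionMeans <- function(atlas) {
  hemi <- hemispheres(atlas)
  pos <- integer(nRegions(atlas))
  for (h in c("left", "right")) {
    idx <- which(hemi == h)
    pos[idx] <- seq_along(idx)
  }
  2.5 + 0.3 * cos(2 * pi * (pos - 1) / max(pos))
}

#' Exchangeable-groups cohort configuration
#'
#' Both groups share the same loading structure: a weak global factor on
#' every region (overall cortical covariance) plus four homotopic community
#' factors, with moderate noise. Since the two groups differ in nothing but
#' their independently drawn subjects, group labels are exchangeable and the
#' configuration is the reference for type-I-error experiments.
#'
#' Default scale: region means around 2.5 mm, loadings 0.06 mm (global) and
#' 0.07 mm (community), noise 0.10 mm, giving within-community population
#' correlations near 0.46 and between-community correlations near 0.20 -
#' moderate covariance typical of thickness SCN matrices.
#'
#' @param atlas a [BrainAtlas].
#' @param seed master seed.
#' @param nPerGroup subjects per group (default 23, the study size).
#' @return a [CohortConfig] with `loadingsA == loadingsB`.
#' @export
nullConfig <- function(atlas, seed = 1L, nPerGroup = 23L) {
  n <- nRegions(atlas)
  nComm <- 4L
  comm <- homotopicCommunities(atlas, nComm)
  L <- matrix(0, n, nComm + 1L)
  L[, 1L] <- 0.06
  L[cbind(seq_len(n), comm + 1L)] <- 0.07
  cohortConfig(atlas, L, L, regionMeans = defaultRegionMeans(atlas),
               nPerGroup = nPerGroup, noiseSd = 0.10, seed = seed)
}

#' Cohort configuration with a planted group covariance contrast
#'
#' Starts from [nullConfig()] and raises the covariance homogeneity of
#' group B: its community loadings are shrunk by the factor
#' `1 - effectSize` while the global loading is boosted so that each
#' region's total signal variance is preserved. Group B's inter-regional
#' correlations become nearly uniform, so at matched density its
#' thresholded network spreads edges randomly instead of concentrating them
#' inside communities - it is more integrated (higher global efficiency,
#' shorter paths) and less modular than group A's at every density, even
#' though edge counts are identical.
#'
#' @param atlas a [BrainAtlas].
#' @param seed master seed.
#' @param effectSize in `[0, 1]`: 0 reduces to the null configuration, 1
#'   removes group B's community structure entirely.
#' @param nPerGroup subjects per group.
#' @return a [CohortConfig].
#' @export
effectConfig <- function(atlas, seed = 1L, effectSize = 0.5,
                         nPerGroup = 23L) {
  if (effectSize < 0 || effectSize > 1)
    stopf("effectSize must lie in [0, 1]")
  cfg <- nullConfig(atlas, seed = seed, nPerGroup = nPerGroup)
  LA <- cfg@loadingsA
  comm <- LA[, -1L, drop = FALSE] * (1 - effectSize)
  global2 <- rowSums(LA^2) - rowSums(comm^2)
  LB <- cbind(sqrt(global2), comm)
  cfg@loadingsB <- LB
  methods::validObject(cfg)
  cfg
}

#' Cohort configuration with a planted connector hub
#'
#' Regions are split into eight homotopic communities, each loading 0.12 mm
#' on its own factor (within-community correlation about 0.88); the chosen
#' hub region instead loads 0.045 mm on every factor. Its population
#' correlation with each community (about 0.31) exceeds the zero
#' between-community correlation, so after density thresholding the hub is
#' the main bridge between communities: shortest paths concentrate on it and
#' its betweenness dwarfs the rest of the network. Both groups share the
#' structure.
#'
#' @param atlas a [BrainAtlas].
#' @param hubRegion region column name (e.g. `"lh_insula"`).
#' @param seed master seed.
#' @param nPerGroup subjects per group.
#' @return a [CohortConfig].
#' @export
hubConfig <- function(atlas, hubRegion, seed = 1L, nPerGroup = 23L) {
  cols <- regionColumns(atlas)
  if (!(hubRegion %in% cols))
    stopf("unknown region '%s' for atlas '%s'", hubRegion, atlas@name)
  n <- nRegions(atlas)
  nComm <- 8L
  comm <- homotopicCommunities(atlas, nComm)
  L <- matrix(0, n, nComm)
  L[cbind(seq_len(n), comm)] <- 0.12
  L[match(hubRegion, cols), ] <- 0.045
  cohortConfig(atlas, L, L, regionMeans = defaultRegionMeans(atlas),
               nPerGroup = nPerGroup, noiseSd = 0.045, seed = seed)
}

# Truncated-normal draws via the inverse-CDF method (exact, rejection-free,
# and deterministic given the RNG stream).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a two-group cohort from a generative configuration
#'
#' Draws ages, factor scores and residual noise from independent substreams
#' of the configuration seed and assembles thickness as
#' `mean + slope * age + loadings %*% factors + noise` per subject (see
#' [CohortConfig]). Within a group, the expected covariance of regions
#' \eqn{i, j} is \eqn{(L L^\top)_{ij} + \sigma^2 1[i=j]} plus the
#' age-induced term \eqn{\beta_i \beta_j \mathrm{Var(age)}}.
#'
#' @param config a [CohortConfig].
#' @return a [ThicknessExperiment] with `2 * nPerGroup` subjects labelled
#'   `"groupA"` / `"groupB"`. Identical configurations (including seed)
#'   yield identical tables.
#' @examples
#' te <- generateCohort(nullConfig(builtinAtlas("desikan_killiany_68"),
#'                                 seed = 7))
#' te
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  n <- config@nPerGroup
  nr <- nRegions(config@atlas)
  nf <- config@nFactors
  ns <- 2L * n
  seeds <- deriveSeeds(config@seed, 3L)

  set.seed(seeds[1L])
  age <- rtruncnorm(ns, config@ageMean, config@ageSd,
                    config@ageRange[1L], config@ageRange[2L])
  set.seed(seeds[2L])
  scores <- matrix(stats::rnorm(ns * nf), ns, nf)
  set.seed(seeds[3L])
  eps <- matrix(stats::rnorm(ns * nr, sd = config@noiseSd), ns, nr)

  idxA <- seq_len(n)
  signal <- rbind(scores[idxA, , drop = FALSE] %*% t(config@loadingsA),
                  scores[-idxA, , drop = FALSE] %*% t(config@loadingsB))
  x <- rep(1, ns) %o% config@regionMeans + age %o% config@ageSlopes +
    signal + eps
  colnames(x) <- regionColumns(config@atlas)
  rownames(x) <- sprintf("sub-%03d", seq_len(ns))
  suppressWarnings(
    ThicknessExperiment(x, group = rep(c("groupA", "groupB"), each = n),
                        age = age, atlas = config@atlas))
}

#' Serialize / restore a cohort configuration as YAML
#'
#' The atlas is stored by name when it is a bundled one, otherwise inline.
#'
#' @param config a [CohortConfig].
#' @param path YAML file path.
#' @return `writeCohortConfig` invisibly returns `path`;
#'   `readCohortConfig` returns a [CohortConfig].
#' @export
writeCohortConfig <- function(config, path) {
  atl <- config@atlas
  builtin <- atl@name %in% c("desikan_killiany_68", "destrieux_148")
  obj <- list(
    atlas = if (builtin) atl@name else
      list(name = atl@name, label = atl@regions$label,
           hemisphere = atl@regions$hemisphere),
    n_per_group = config@nPerGroup, n_factors = config@nFactors,
    loadings_A = as.list(as.data.frame(config@loadingsA)),
    loadings_B = as.list(as.data.frame(config@loadingsB)),
    region_means = config@regionMeans, age_mean = config@ageMean,
    age_sd = config@ageSd, age_range = config@ageRange,
    age_slopes = config@ageSlopes, noise_sd = config@noiseSd,
    seed = config@seed)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  atl <- if (is.character(obj$atlas)) builtinAtlas(obj$atlas) else
    BrainAtlas(obj$atlas$name, obj$atlas$label, obj$atlas$hemisphere)
  toMat <- function(l) do.call(cbind, lapply(l, as.numeric))
  cohortConfig(atl, toMat(obj$loadings_A), toMat(obj$loadings_B),
               regionMeans = obj$region_means, ageSlopes = obj$age_slopes,
               nPerGroup = obj$n_per_group, ageMean = obj$age_mean,
               ageSd = obj$age_sd, ageRange = obj$age_range,
               noiseSd = obj$noise_sd, seed = obj$seed)
}

#' @rdname atlas
#' @export
setMethod("atlas", "CohortConfig", function(x) x@atlas)

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: 2 x %d subjects, %d regions ('%s'), %d factors, seed %d\n",
    object@nPerGroup, nRegions(object@atlas), object@atlas@name,
    object@nFactors, object@seed))
  same <- identical(object@loadingsA, object@loadingsB)
  cat(if (same) "  groups share loadings (null configuration)\n"
      else "  group-specific loadings (planted contrast)\n")
})
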