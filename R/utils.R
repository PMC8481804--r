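# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for edge counts: `round()` in R rounds half
#' to even, which would make thresholded edge counts platform-convention
#' dependent; half-away-from-zero keeps `K = round(D * n(n-1)/2)` bit-exact.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
roundHalfUp <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Upper-triangle (i < j) index pairs of an n x n matrix, column-major order.
upperPairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)))
  list(i = ((idx - 1L) %% n) + 1L, j = ((idx - 1L) %/% n) + 1L, flat = idx)
}

# Derive k reproducible child seeds from one master seed without leaking
# state between components (each child stream is seeded independently).
deriveSeeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

# Full-precision numeric formatting for lossless TSV round trips.
fmtNum <- function(x) {
  sprintf("%.17g", x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
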