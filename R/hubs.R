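#' @include metrics.R
NULL

#' Identify hubs by the betweenness z-threshold
#'
#' A region is a hub when its betweenness centrality is at least
#' `mean + k * sd` of the betweenness over all regions (`k = 2` by default,
#' inclusive comparison). The standard deviation defaults to the population
#' form: the atlas region set is a census, not a sample. When the
#' betweenness is constant (sd = 0) no region stands out and the hub set is
#' empty, with a warning.
#'
#' @param x a named per-region betweenness vector, or a [BinaryNetwork]
#'   (betweenness is computed via [betweennessCentrality()]).
#' @param k z-threshold multiplier.
#' @param sdType `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @param group optional group label carried into the report.
#' @param density density the network was thresholded at (taken from the
#'   network when `x` is a [BinaryNetwork]).
#' @return a [HubReport]; hubs are sorted by decreasing betweenness.
#' @examples
#' identifyHubs(c(a = 0, b = 1, c = 0))  # path graph: no hubs at k = 2
#' @export
identifyHubs <- function(x, k = 2, sdType = c("population", "sample"),
                         group = "", density = NA_real_) {
  sdType <- match.arg(sdType)
  if (methods::is(x, "BinaryNetwork")) {
    if (is.na(density)) density <- networkDensity(x)
    b <- betweennessCentrality(x)
  } else {
    b <- x
  }
  if (length(b) < 2L) stopf("hub identification needs at least 2 nodes")
  if (is.null(names(b))) names(b) <- paste0("node", seq_along(b))
  n <- length(b)
  mu <- mean(b)
  sdv <- stats::sd(b) * if (sdType == "population") sqrt((n - 1) / n) else 1
  thr <- mu + k * sdv
  if (sdv == 0) {
    warnf("betweenness is constant (sd = 0); empty hub set")
    hubs <- character(0)
  } else {
    hubs <- names(b)[b >= thr]
    hubs <- hubs[order(-b[hubs])]
  }
  methods::new("HubReport", group = group, density = density, hubs = hubs,
               betweenness = b, bMean = mu, bSd = sdv, threshold = thr,
               k = k)
}

#' @rdname hubRegions
#' @export
setMethod("hubRegions", "HubReport", function(x) x@hubs)

setMethod("show", "HubReport", function(object) {
  cat(sprintf("HubReport%s%s: %d hub(s) of %d regions\n",
              if (nzchar(object@group)) paste0(" '", object@group, "'") else "",
              if (!is.na(object@density))
                sprintf(" at density %.3g", object@density) else "",
              length(object@hubs), length(object@betweenness)))
  cat(sprintf("  threshold = mean + %.3g*sd = %.4g + %.3g*%.4g = %.4g\n",
              object@k, object@bMean, object@k, object@bSd,
              object@threshold))
  if (length(object@hubs))
    cat("  hubs:", paste(object@hubs, collapse = ", "), "\n")
})

#' Compare the hub sets of two groups
#'
#' @param reportA,reportB [HubReport]s computed over the same region set.
#' @return `list(shared = , onlyA = , onlyB = )` partitioning the union of
#'   the two hub lists.
#' @export
compareHubs <- function(reportA, reportB) {
  if (!setequal(names(reportA@betweenness), names(reportB@betweenness)))
    stopf("hub reports cover different region sets (atlas mismatch?)")
  a <- hubRegions(reportA)
  b <- hubRegions(reportB)
  list(shared = intersect(a, b),
       onlyA = setdiff(a, b),
       onlyB = setdiff(b, a))
}

#' Serialize a hub report as JSON
#'
#' @param report a [HubReport].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeHubReport <- function(report, path) {
  jsonlite::write_json(list(
    group = report@group, density = report@density, k = report@k,
    betweenness_mean = report@bMean, betweenness_sd = report@bSd,
    threshold = report@threshold, hubs = report@hubs,
    betweenness = as.list(report@betweenness)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
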