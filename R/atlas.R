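#' @include AllGenerics.R
NULL

#' Construct an atlas definition
#'
#' @param name atlas identifier.
#' @param labels region labels (shared between hemispheres or already
#'   hemisphere-specific, matched one-to-one with `hemisphere`).
#' @param hemisphere per-region hemisphere tag, `"left"` or `"right"`.
#' @return a [BrainAtlas].
#' @examples
#' BrainAtlas("toy4", c("a", "b", "a", "b"),
#'            c("left", "left", "right", "right"))
#' @export
BrainAtlas <- function(name, labels, hemisphere) {
  methods::new("BrainAtlas", name = name,
               regions = data.frame(label = as.character(labels),
                                    hemisphere = as.character(hemisphere),
                                    stringsAsFactors = FALSE))
}

#' Load a bundled atlas
#'
#' The package ships the two cortical parcellations used for structural
#' covariance work on FreeSurfer output: the Desikan-Killiany atlas
#' (`"desikan_killiany_68"`, 34 regions per hemisphere) and the finer
#' Destrieux atlas (`"destrieux_148"`, 74 per hemisphere).
#'
#' @param name one of `"desikan_killiany_68"`, `"destrieux_148"`.
#' @return a [BrainAtlas].
#' @examples
#' dk <- builtinAtlas("desikan_killiany_68")
#' nRegions(dk)
#' @export
builtinAtlas <- function(name) {
  known <- c("desikan_killiany_68", "destrieux_148")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stopf("atlas not found: '%s' (available: %s)",
          as.character(name)[1], paste(known, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".json"), package = "scnet",
                      mustWork = TRUE)
  readAtlasJSON(path)
}

#' Read an atlas from its JSON serialization
#'
#' The format is `{"name": ..., "regions": [{"label":..., "hemisphere":...}]}`,
#' the same layout the bundled atlases use, so site-specific parcellations
#' can be supplied as plain files.
#'
#' @param path JSON file path.
#' @return a [BrainAtlas].
#' @export
readAtlasJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("BrainAtlas", name = obj$name,
               regions = data.frame(label = obj$regions$label,
                                    hemisphere = obj$regions$hemisphere,
                                    stringsAsFactors = FALSE))
}

#' @rdname nRegions
#' @export
setMethod("nRegions", "BrainAtlas", function(x) nrow(x@regions))

#' @rdname regionColumns
#' @export
setMethod("regionColumns", "BrainAtlas", function(x) {
  prefix <- ifelse(x@regions$hemisphere == "left", "lh_", "rh_")
  paste0(prefix, x@regions$label)
})

#' @rdname hemispheres
#' @export
setMethod("hemispheres", "BrainAtlas", function(x) x@regions$hemisphere)

setMethod("show", "BrainAtlas", function(object) {
  h <- table(factor(object@regions$hemisphere, c("left", "right")))
  cat(sprintf("BrainAtlas '%s': %d regions (%d left, %d right)\n",
              object@name, nRegions(object), h[["left"]], h[["right"]]))
})
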