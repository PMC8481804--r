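#' @include atlas.R
NULL

#' Build a ThicknessExperiment from matrices and covariates
#'
#' @param thickness numeric matrix, one row per subject, one column per atlas
#'   region; column names must cover `regionColumns(atlas)` (any order -
#'   columns are reordered to atlas order).
#' @param group per-subject group labels.
#' @param age per-subject ages in years.
#' @param atlas a [BrainAtlas].
#' @param subjectIds subject identifiers; defaults to the rownames of
#'   `thickness`.
#' @param residualized set `TRUE` when `thickness` holds signed residuals
#'   rather than raw millimetres.
#' @return a [ThicknessExperiment].
#' @examples
#' atl <- BrainAtlas("toy2", c("a", "a"), c("left", "right"))
#' x <- matrix(2.5 + rnorm(8, sd = 0.1), 4,
#'             dimnames = list(paste0("s", 1:4), c("lh_a", "rh_a")))
#' te <- ThicknessExperiment(x, rep(c("g1", "g2"), 2), c(30, 40, 50, 60), atl)
#' @export
ThicknessExperiment <- function(thickness, group, age, atlas,
                                subjectIds = rownames(thickness),
                                residualized = FALSE) {
  thickness <- as.matrix(thickness)
  if (!is.numeric(thickness))
    stopf("thickness values must be numeric")
  cols <- regionColumns(atlas)
  missing <- setdiff(cols, colnames(thickness))
  if (length(missing))
    stopf("thickness table is missing region column(s): %s",
          paste(missing, collapse = ", "))
  thickness <- thickness[, cols, drop = FALSE]
  if (is.null(subjectIds)) subjectIds <- paste0("sub-", seq_len(nrow(thickness)))
  if (length(group) != nrow(thickness) || length(age) != nrow(thickness) ||
      length(subjectIds) != nrow(thickness))
    stopf("'group', 'age' and 'subjectIds' need one entry per subject")
  rownames(thickness) <- as.character(subjectIds)
  if (!residualized) checkThicknessRange(thickness)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(thickness = t(thickness)),
    rowData = S4Vectors::DataFrame(
      label = atlas@regions$label, hemisphere = atlas@regions$hemisphere,
      row.names = cols),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   age = as.numeric(age),
                                   row.names = as.character(subjectIds)))
  S4Vectors::metadata(se)$residualized <- isTRUE(residualized)
  methods::new("ThicknessExperiment", se, atlas = atlas)
}

# Plausibility screen: cortex is roughly 1-4.5 mm thick; values outside
# (0.5, 6) are suspicious but must not block synthetic extremes.
checkThicknessRange <- function(x) {
  if (anyNA(x) || !is.numeric(x))
    stopf("thickness values must be numeric with no missing cells")
  if (any(x <= 0))
    stopf("thickness values must be strictly positive (mm)")
  n <- sum(x <= 0.5 | x >= 6.0)
  if (n > 0)
    warnf("%d thickness value(s) outside the plausible (0.5, 6.0) mm range", n)
  invisible(TRUE)
}

#' @rdname atlas
#' @export
setMethod("atlas", "ThicknessExperiment", function(x) x@atlas)

#' @rdname thicknessValues
#' @export
setMethod("thicknessValues", "ThicknessExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "thickness"))
})

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "ThicknessExperiment", function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
})

#' @rdname subjectAges
#' @export
setMethod("subjectAges", "ThicknessExperiment", function(x) {
  as.numeric(SummarizedExperiment::colData(x)$age)
})

setMethod("show", "ThicknessExperiment", function(object) {
  g <- table(groupLabels(object))
  cat(sprintf("ThicknessExperiment: %d subjects x %d regions (atlas '%s')\n",
              ncol(object), nrow(object), object@atlas@name))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(g), g), collapse = ", "),
      "\n")
  if (isTRUE(S4Vectors::metadata(object)$residualized))
    cat("  values are age-adjusted residuals\n")
})

#' Read a thickness table and its covariates from TSV files
#'
#' The thickness file follows FreeSurfer's `aparcstats2table` dialect: a
#' header row, a subject-id column first, then one `lh_<label>` /
#' `rh_<label>` column per atlas region (extra columns are ignored, any
#' column order is accepted). The covariate file has columns `subject_id`,
#' `group`, `age`. Subjects are joined by id and must be present in both
#' files.
#'
#' @param thicknessPath,covariatesPath TSV file paths.
#' @param atlas a [BrainAtlas]; region columns are reordered to its order.
#' @return a validated [ThicknessExperiment].
#' @seealso [writeThicknessTable()]
#' @export
readThicknessTable <- function(thicknessPath, covariatesPath, atlas) {
  th <- utils::read.delim(thicknessPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cv <- utils::read.delim(covariatesPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(th) < 2L) stopf("thickness file needs an id column plus regions")
  ids <- as.character(th[[1L]])
  cols <- regionColumns(atlas)
  missing <- setdiff(cols, colnames(th))
  if (length(missing))
    stopf("thickness file is missing region column(s): %s",
          paste(missing, collapse = ", "))
  x <- as.matrix(th[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  need <- c("subject_id", "group", "age")
  if (!all(need %in% colnames(cv)))
    stopf("covariate file needs columns: %s", paste(need, collapse = ", "))
  cids <- as.character(cv$subject_id)
  onlyT <- setdiff(ids, cids); onlyC <- setdiff(cids, ids)
  if (length(onlyT) || length(onlyC))
    stopf("subject id mismatch between files (thickness only: %s; covariates only: %s)",
          paste(onlyT, collapse = ","), paste(onlyC, collapse = ","))
  if (anyDuplicated(ids) || anyDuplicated(cids))
    stopf("duplicated subject ids")
  m <- match(ids, cids)
  ThicknessExperiment(x, group = cv$group[m], age = as.numeric(cv$age[m]),
                      atlas = atlas, subjectIds = ids)
}

#' Write a thickness table and covariates as TSV files
#'
#' Values are written at full double precision so that
#' `readThicknessTable()` reproduces the table exactly.
#'
#' @param x a [ThicknessExperiment] with at least one subject.
#' @param thicknessPath,covariatesPath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeThicknessTable <- function(x, thicknessPath, covariatesPath) {
  if (ncol(x) == 0L) stopf("refusing to write an empty table (no subjects)")
  vals <- thicknessValues(x)
  th <- data.frame(subject_id = rownames(vals), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (cn in colnames(vals)) th[[cn]] <- fmtNum(vals[, cn])
  cv <- data.frame(subject_id = rownames(vals), group = groupLabels(x),
                   age = fmtNum(subjectAges(x)), stringsAsFactors = FALSE)
  for (p in c(thicknessPath, covariatesPath))
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(th, thicknessPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(cv, covariatesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(thickness = thicknessPath, covariates = covariatesPath))
}
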