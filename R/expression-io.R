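#' Construct an expression matrix object
#'
#' The central container of the package: a features x samples matrix of log2
#' intensities together with an aligned sample sheet. All downstream analysis
#' (filtering, differential expression, profiles, clustering) operates on this
#' object. Values are assumed to be normalized log2 intensities; no
#' re-normalization is performed.
#'
#' @param values numeric matrix, features x samples, finite, with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param samples data.frame with columns `sample_id`, `stage`, `sex`
#'   (one of "M", "F", "mixed") and `replicate`; one row per matrix column,
#'   matched by `sample_id`.
#' @param feature_kind "gene" or "miRNA".
#' @param stage_levels ordered character vector of stage labels; defaults to
#'   the stages present in `samples` in order of first appearance.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `samples`, `feature_kind`, `stage_levels`.
#' @export
expression_matrix <- function(values, samples, feature_kind = c("gene", "miRNA"),
                              stage_levels = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0L &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("`values` must have unique rownames (feature ids)")
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (is.null(colnames(values)))
    stop("`values` must have colnames (sample ids)")
  if (any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  required <- c("sample_id", "stage", "sex", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  only_matrix <- setdiff(colnames(values), samples$sample_id)
  only_sheet  <- setdiff(samples$sample_id, colnames(values))
  if (length(only_matrix) || length(only_sheet))
    stop("sample mismatch between matrix and sheet; only in matrix: [",
         paste(only_matrix, collapse = ", "), "]; only in sheet: [",
         paste(only_sheet, collapse = ", "), "]")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$stage <- as.character(samples$stage)
  if (is.null(stage_levels)) stage_levels <- unique(samples$stage)
  bad_stage <- setdiff(samples$stage, stage_levels)
  if (length(bad_stage))
    stop("stages not in stage_levels: ", paste(unique(bad_stage), collapse = ", "))
  if (!all(samples$sex %in% c("M", "F", "mixed")))
    stop("sex must be one of 'M', 'F', 'mixed'")
  structure(list(values = values, samples = samples,
                 feature_kind = feature_kind, stage_levels = stage_levels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d features x %d samples, %d stages\n",
              x$feature_kind, nrow(x$values), ncol(x$values),
              length(x$stage_levels)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample sheet from TSV files
#'
#' The matrix file has a header of sample ids and a first column `feature_id`;
#' the sample sheet has columns `sample_id`, `stage`, `sex`, `replicate`.
#' Samples present in only one of the two files are an error.
#'
#' @param matrix_path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @param feature_kind "gene" or "miRNA".
#' @param stage_levels optional ordered stage labels (defaults to order of
#'   appearance in the sheet).
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(matrix_path, sample_sheet_path,
                            feature_kind = c("gene", "miRNA"),
                            stage_levels = NULL) {
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id")
    stop("expression matrix must have `feature_id` as its first column")
  if (anyDuplicated(tab$feature_id))
    stop("duplicated feature ids in ", matrix_path)
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   names(vals)[j], bad, matrix_path))
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- tab$feature_id
  samples <- utils::read.delim(sample_sheet_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  em <- expression_matrix(values, samples, feature_kind, stage_levels)
  message(sprintf("read %d %s features x %d samples", nrow(values),
                  feature_kind, ncol(values)))
  em
}

#' Write an expression matrix (and optionally its sample sheet) to TSV
#'
#' @param em an [expression_matrix()] object.
#' @param matrix_path output path for the expression TSV.
#' @param sample_sheet_path optional output path for the sample sheet TSV.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(em, matrix_path, sample_sheet_path = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  out <- data.frame(feature_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(em$samples, sample_sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Collapse redundant features (probes) to one row per entity
#'
#' Microarray platforms carry several probe sets per gene. The representative
#' row for each entity is, by default, the probe with the highest mean
#' intensity over all samples; "max_variance" picks the most variable probe
#' instead. Unmapped features are dropped.
#'
#' @param em an [expression_matrix()] object.
#' @param mapping data.frame with columns `feature_id`, `entity_id`.
#' @param rule "max_mean" (default) or "max_variance".
#' @return An [expression_matrix()] with one row per mapped entity.
#' @export
collapse_features <- function(em, mapping, rule = c("max_mean", "max_variance")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  rule <- match.arg(rule)
  if (!all(c("feature_id", "entity_id") %in% names(mapping)))
    stop("mapping must have columns feature_id, entity_id")
  mapping <- mapping[mapping$feature_id %in% rownames(em$values), , drop = FALSE]
  if (nrow(mapping) == 0L) stop("empty mapping: no features map to entities")
  stat <- if (rule == "max_mean") rowMeans(em$values)
          else apply(em$values, 1, stats::var)
  mapping$stat <- stat[mapping$feature_id]
  # deterministic: ties broken by feature id order
  mapping <- mapping[order(mapping$entity_id, -mapping$stat, mapping$feature_id), ]
  keep <- mapping[!duplicated(mapping$entity_id), , drop = FALSE]
  values <- em$values[keep$feature_id, , drop = FALSE]
  rownames(values) <- keep$entity_id
  expression_matrix(values, em$samples, em$feature_kind, em$stage_levels)
}

#' Embryonic (developmental) stages of an ExpressionMatrix
#'
#' Mature stages are identified by label: any stage not starting with "E" is
#' treated as post-developmental (e.g. "young", "old").
#'
#' @param em an [expression_matrix()] object or a character vector of stages.
#' @return Character vector of embryonic stage labels, in order.
#' @export
dev_stages <- function(em) {
  stages <- if (inherits(em, "ExpressionMatrix")) em$stage_levels else em
  stages[startsWith(stages, "E")]
}

#' Per-stage replicate-mean profiles
#'
#' Averages log2 intensities over the replicates of each stage, yielding one
#' stage profile per feature. With `dev_only = TRUE` only embryonic stages
#' (labels starting with "E") are retained, the form used for
#' developmental-only correlations.
#'
#' @param em an [expression_matrix()] object.
#' @param dev_only restrict to embryonic stages?
#' @return Numeric matrix features x stages with class attribute
#'   `"StageProfileMatrix"`; `attr(, "dev_only")` records the flag.
#' @export
stage_means <- function(em, dev_only = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  stages <- em$stage_levels
  if (dev_only) stages <- dev_stages(em)
  if (!length(stages)) stop("no stages selected")
  prof <- vapply(stages, function(s) {
    idx <- which(em$samples$stage == s)
    if (!length(idx)) stop("stage with zero samples: ", s)
    rowMeans(em$values[, idx, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (nrow(em$values) == 1L) prof <- matrix(prof, nrow = 1,
                                            dimnames = list(rownames(em$values), stages))
  attr(prof, "dev_only") <- dev_only
  class(prof) <- c("StageProfileMatrix", class(prof))
  prof
}

#' Filter features by the expression threshold
#'
#' A feature counts as expressed when its maximum per-stage replicate mean is
#' strictly greater than `threshold` (default 5 on the log2 scale) at one
#' stage at least. Returns the kept matrix and the ids that were dropped.
#'
#' @param em an [expression_matrix()] object.
#' @param threshold log2-intensity expression threshold.
#' @return List with `matrix` (filtered [expression_matrix()]) and
#'   `dropped` (character vector of removed feature ids).
#' @export
filter_expressed <- function(em, threshold = 5) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  prof <- stage_means(em)
  keep <- apply(prof, 1, max) > threshold
  dropped <- rownames(em$values)[!keep]
  values <- em$values[keep, , drop = FALSE]
  list(matrix = expression_matrix(values, em$samples, em$feature_kind,
                                  em$stage_levels),
       dropped = dropped)
}
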