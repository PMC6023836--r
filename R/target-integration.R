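#' Read a miRNA-target interaction table for one resource
#'
#' Expects a TSV with columns `mirna_id`, `gene_id` and optionally `score`
#' and `reference_ids`. Records are tagged with the resource name and
#' evidence type. Duplicate (mirna, gene) pairs within one file keep the best
#' score for the resource's direction.
#'
#' @param path TSV path.
#' @param resource resource name.
#' @param evidence "predicted" or "experimental".
#' @param direction "higher" or "lower" is better (used for deduplication of
#'   predicted records).
#' @return data.frame with columns mirna_id, gene_id, resource, evidence,
#'   score, reference_ids.
#' @export
read_interactions <- function(path, resource,
                              evidence = c("predicted", "experimental"),
                              direction = c("higher", "lower")) {
  evidence <- match.arg(evidence)
  direction <- match.arg(direction)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("mirna_id", "gene_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("interaction file lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(tab$score)) tab$score <- NA_real_
  if (is.null(tab$reference_ids)) tab$reference_ids <- NA_character_
  key <- paste(tab$mirna_id, tab$gene_id)
  if (anyDuplicated(key)) {
    ord <- if (direction == "higher") order(key, -tab$score)
           else order(key, tab$score)
    tab <- tab[ord, , drop = FALSE]
    dup <- duplicated(paste(tab$mirna_id, tab$gene_id))
    message(sprintf("%s: %d duplicate pairs collapsed (kept best score)",
                    resource, sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  data.frame(mirna_id = tab$mirna_id, gene_id = tab$gene_id,
             resource = resource, evidence = evidence, score = tab$score,
             reference_ids = tab$reference_ids, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Apply per-resource score cutoffs
#'
#' Predicted records must pass their resource's recommended cutoff
#' (direction-aware, inclusive); experimental records are always retained.
#'
#' @param records interaction data.frame (see [read_interactions()]).
#' @param cutoffs named list; each element a list with `threshold` and
#'   `direction` ("higher"/"lower" is better). Every predicted resource in
#'   `records` must be configured.
#' @return Filtered data.frame.
#' @export
filter_by_score <- function(records, cutoffs) {
  pred_res <- unique(records$resource[records$evidence == "predicted"])
  missing_cfg <- setdiff(pred_res, names(cutoffs))
  if (length(missing_cfg))
    stop("no score cutoff configured for predicted resource(s): ",
         paste(missing_cfg, collapse = ", "))
  keep <- records$evidence == "experimental"
  for (r in pred_res) {
    cfg <- cutoffs[[r]]
    idx <- records$resource == r
    pass <- if (cfg$direction == "higher") records$score >= cfg$threshold
            else records$score <= cfg$threshold
    keep <- keep | (idx & !is.na(pass) & pass)
  }
  records[keep, , drop = FALSE]
}

#' Convert resource scores to percentiles
#'
#' Within one resource, scored records are ranked from best to worst
#' (direction-aware); tied scores share the best (minimum) rank of their tie
#' group. The percentile is ceiling(100 * rank / N), so percentile 1 marks
#' the top 1% of scores.
#'
#' @param records interaction data.frame.
#' @param resource resource whose records to convert.
#' @param direction "higher" or "lower" scores are better.
#' @return `records` with a `percentile` column filled for this resource
#'   (experimental records keep NA).
#' @export
score_to_percentile <- function(records, resource,
                                direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (is.null(records$percentile)) records$percentile <- NA_integer_
  idx <- which(records$resource == resource & records$evidence == "predicted")
  if (!length(idx)) return(records)
  sc <- records$score[idx]
  if (anyNA(sc)) stop("unscored predicted records for resource ", resource)
  key <- if (direction == "higher") -sc else sc
  rank_min <- rank(key, ties.method = "min")
  records$percentile[idx] <- as.integer(ceiling(100 * rank_min / length(idx)))
  records
}

#' Keep interactions whose partners are expressed
#'
#' @param records interaction data.frame.
#' @param expressed_genes,expressed_mirnas character id sets from
#'   [filter_expressed()].
#' @param mode "both" (default): both partners must be expressed;
#'   "either": at least one.
#' @return Filtered data.frame.
#' @export
restrict_to_expressed <- function(records, expressed_genes, expressed_mirnas,
                                  mode = c("both", "either")) {
  mode <- match.arg(mode)
  g <- records$gene_id %in% expressed_genes
  m <- records$mirna_id %in% expressed_mirnas
  keep <- if (mode == "both") g & m else g | m
  message(sprintf("expression restriction (%s): kept %d of %d interactions",
                  mode, sum(keep), nrow(records)))
  records[keep, , drop = FALSE]
}

#' Merge per-resource interaction sets
#'
#' Unions records keyed by (mirna, gene, resource) and builds a per-pair
#' summary listing supporting resources, the best percentile across
#' resources, and whether experimental support exists.
#'
#' @param ... interaction data.frames (individually filtered).
#' @return List with `records` (union, deterministically sorted) and
#'   `pairs` (one row per (mirna, gene): n_resources, resources, evidence
#'   flag, best_percentile).
#' @export
merge_resources <- function(...) {
  inputs <- list(...)
  inputs <- inputs[vapply(inputs, function(x) !is.null(x) && nrow(x) > 0,
                          logical(1))]
  if (!length(inputs)) {
    empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                        resource = character(0), evidence = character(0),
                        score = numeric(0), percentile = integer(0))
    return(list(records = empty,
                pairs = data.frame(mirna_id = character(0),
                                   gene_id = character(0),
                                   n_resources = integer(0),
                                   resources = character(0),
                                   has_experimental = logical(0),
                                   best_percentile = integer(0))))
  }
  for (i in seq_along(inputs))
    if (is.null(inputs[[i]]$percentile)) inputs[[i]]$percentile <- NA_integer_
  cols <- c("mirna_id", "gene_id", "resource", "evidence", "score", "percentile")
  rec <- do.call(rbind, lapply(inputs, function(x) x[, cols]))
  key3 <- paste(rec$mirna_id, rec$gene_id, rec$resource)
  rec <- rec[!duplicated(key3), , drop = FALSE]
  rec <- rec[order(rec$mirna_id, rec$gene_id, rec$resource), , drop = FALSE]
  rownames(rec) <- NULL
  key2 <- paste(rec$mirna_id, rec$gene_id, sep = "\r")
  split_idx <- split(seq_len(nrow(rec)), key2)
  pairs <- do.call(rbind, lapply(split_idx, function(ii) {
    pr <- rec[ii, , drop = FALSE]
    bp <- suppressWarnings(min(pr$percentile, na.rm = TRUE))
    data.frame(mirna_id = pr$mirna_id[1], gene_id = pr$gene_id[1],
               n_resources = length(ii),
               resources = paste(sort(pr$resource), collapse = ","),
               has_experimental = any(pr$evidence == "experimental"),
               best_percentile = if (is.finite(bp)) as.integer(bp) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[order(pairs$mirna_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(records = rec, pairs = pairs)
}
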