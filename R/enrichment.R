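#' Hypergeometric overrepresentation test over flat categories
#'
#' For each category, tests whether the query set overlaps the category more
#' than expected when drawing n genes from a universe of N containing K
#' annotated genes: p = P[X >= k] for X ~ Hypergeometric(N, K, n), followed
#' by Benjamini-Hochberg adjustment across the tested categories. Query
#' genes outside the universe are dropped with a warning; category sets are
#' intersected with the universe.
#'
#' @param query character vector of gene ids.
#' @param categories named list mapping category id to a character vector of
#'   gene ids, or a data.frame with columns `gene_id`, `category`.
#' @param universe character vector of gene ids (the background).
#' @return data.frame sorted by fdr with columns category, k, K, n, N,
#'   p_raw, fdr.
#' @export
hypergeom_enrichment <- function(query, categories, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (is.data.frame(categories))
    categories <- split(categories$gene_id, categories$category)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe were dropped")
    query <- intersect(query, universe)
  }
  query <- unique(query)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(categories), function(cat) {
    K_set <- intersect(unique(categories[[cat]]), universe)
    K <- length(K_set)
    k <- length(intersect(query, K_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      fdr = numeric(0)))
  out$fdr <- adjust_bh(out$p_raw)
  out <- out[order(out$fdr, out$p_raw, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
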