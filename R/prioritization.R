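#' DETG / DETGNC statistics per miRNA
#'
#' For each miRNA, counts its differentially expressed target genes (DETGs)
#' and the anti-correlated subset (DETGNCs), and reports the percentage
#' 100 * n_DETGNC / n_DETG. miRNAs without any DETG are flagged
#' (`pct_defined = FALSE`) rather than dropped, so the full ranking universe
#' is preserved.
#'
#' @param correlated output of [annotate_correlations()].
#' @param de_gene_ids character vector of differentially expressed gene ids.
#' @param mirna_ids universe of miRNAs to report; defaults to the miRNAs
#'   present in `correlated`.
#' @return data.frame with mirna_id, n_DETG, n_DETGNC, pct_DETGNC,
#'   pct_defined.
#' @export
detg_stats <- function(correlated, de_gene_ids, mirna_ids = NULL) {
  if (is.null(mirna_ids)) mirna_ids <- unique(correlated$mirna_id)
  detg <- correlated[correlated$gene_id %in% de_gene_ids, , drop = FALSE]
  # one target counts once per miRNA even with multi-resource support
  detg <- detg[!duplicated(paste(detg$mirna_id, detg$gene_id)), , drop = FALSE]
  rows <- lapply(mirna_ids, function(m) {
    sub <- detg[detg$mirna_id == m, , drop = FALSE]
    n_detg <- nrow(sub)
    n_nc <- sum(isTRUE_vec(sub$is_anticorrelated))
    data.frame(mirna_id = m, n_DETG = n_detg, n_DETGNC = n_nc,
               pct_DETGNC = if (n_detg > 0) 100 * n_nc / n_detg else NA_real_,
               pct_defined = n_detg > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count anti-correlated transcription-regulator targets per miRNA
#'
#' Shortlists miRNAs whose anti-correlated targets include at least
#' `min_count` genes annotated as transcription regulators; the overlap with
#' heart-development annotation is reported alongside.
#'
#' @param correlated output of [annotate_correlations()].
#' @param annotations data.frame with columns `gene_id`, `category`
#'   (categories include "tx_regulator", "heart_dev").
#' @param min_count shortlist threshold ("min_count or more", inclusive).
#' @return data.frame with mirna_id, n_anticorr_regulators,
#'   n_anticorr_heart_dev, shortlisted.
#' @export
count_anticorr_regulators <- function(correlated, annotations, min_count = 10) {
  txreg <- unique(annotations$gene_id[annotations$category == "tx_regulator"])
  heart <- unique(annotations$gene_id[annotations$category == "heart_dev"])
  anti <- correlated[isTRUE_vec(correlated$is_anticorrelated), , drop = FALSE]
  anti <- anti[!duplicated(paste(anti$mirna_id, anti$gene_id)), , drop = FALSE]
  mirnas <- unique(correlated$mirna_id)
  rows <- lapply(mirnas, function(m) {
    targets <- unique(anti$gene_id[anti$mirna_id == m])
    data.frame(mirna_id = m,
               n_anticorr_regulators = sum(targets %in% txreg),
               n_anticorr_heart_dev = sum(targets %in% heart),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna_id = character(0), n_anticorr_regulators = integer(0),
                      n_anticorr_heart_dev = integer(0))
  out$shortlisted <- out$n_anticorr_regulators >= min_count
  rownames(out) <- NULL
  out
}

#' Stringent candidate filter
#'
#' Retains interactions where both the miRNA and the target gene show at
#' least a 4-fold differential change at some stage (max over contrasts of
#' |log2FC| >= `lfc_threshold`), the Kendall correlation is strictly below
#' `tau_threshold`, and the target is annotated to heart development.
#'
#' @param correlated output of [annotate_correlations()].
#' @param mirna_de,gene_de named numeric vectors: per-feature maximum
#'   |log2FC| over the DE contrasts (see [max_abs_lfc()]).
#' @param annotations annotation data.frame (`gene_id`, `category`).
#' @param lfc_threshold minimum max |log2FC| for both partners (default 2).
#' @param tau_threshold Kendall threshold (default -0.4, strict "<").
#' @param mode which tau is compared: "dev" or "full".
#' @return data.frame of candidate interactions (mirna_id, gene_id, tau,
#'   mirna_max_lfc, gene_max_lfc), deduplicated across resources and sorted
#'   by miRNA then tau.
#' @export
stringent_filter <- function(correlated, mirna_de, gene_de, annotations,
                             lfc_threshold = 2, tau_threshold = -0.4,
                             mode = c("dev", "full")) {
  mode <- match.arg(mode)
  heart <- unique(annotations$gene_id[annotations$category == "heart_dev"])
  tau <- if (mode == "dev") correlated$tau_dev else correlated$tau_full
  keep <- !is.na(tau) & tau < tau_threshold &
    correlated$gene_id %in% heart &
    correlated$mirna_id %in% names(mirna_de) &
    correlated$gene_id %in% names(gene_de)
  sub <- correlated[keep, , drop = FALSE]
  sub <- sub[mirna_de[sub$mirna_id] >= lfc_threshold &
               gene_de[sub$gene_id] >= lfc_threshold, , drop = FALSE]
  sub <- sub[!duplicated(paste(sub$mirna_id, sub$gene_id)), , drop = FALSE]
  out <- data.frame(mirna_id = sub$mirna_id, gene_id = sub$gene_id,
                    tau = if (mode == "dev") sub$tau_dev else sub$tau_full,
                    mirna_max_lfc = unname(mirna_de[sub$mirna_id]),
                    gene_max_lfc = unname(gene_de[sub$gene_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$tau), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum absolute log2 fold change per feature
#'
#' Convenience reduction of a DE result table to the per-feature maximum
#' |log2FC| over all contrasts, the quantity "at least a 4-fold change at
#' one time point" refers to.
#'
#' @param de_results data.frame from [de_vs_reference()].
#' @return Named numeric vector.
#' @export
max_abs_lfc <- function(de_results) {
  tapply(abs(de_results$log2FC), de_results$feature_id, max)
}

#' Template-based detection of co-expressed miRNAs
#'
#' Ranks all miRNAs by the Kendall correlation of their full-series
#' standardized profile with a reference (template) miRNA's profile and
#' returns those at or above the similarity threshold. The template itself
#' is excluded by default.
#'
#' @param template_mirna_id id of the reference miRNA.
#' @param mirna_profiles stage-mean matrix (features x stages).
#' @param similarity_threshold minimum Kendall tau (default 0.6, inclusive).
#' @param include_self keep the template in the output?
#' @return data.frame with mirna_id, tau, sorted by decreasing tau.
#' @export
template_match <- function(template_mirna_id, mirna_profiles,
                           similarity_threshold = 0.6, include_self = FALSE) {
  mirna_profiles <- unclass(mirna_profiles)
  if (!template_mirna_id %in% rownames(mirna_profiles))
    stop("unknown template miRNA: ", template_mirna_id)
  std <- standardize_profiles(mirna_profiles)$profiles
  if (!template_mirna_id %in% rownames(std))
    stop("template profile has zero variance")
  tpl <- std[template_mirna_id, ]
  ids <- rownames(std)
  tau <- vapply(ids, function(m)
    suppressWarnings(kendall_tau(tpl, std[m, ])), numeric(1))
  out <- data.frame(mirna_id = ids, tau = unname(tau), stringsAsFactors = FALSE)
  if (!include_self) out <- out[out$mirna_id != template_mirna_id, , drop = FALSE]
  out <- out[!is.na(out$tau) & out$tau >= similarity_threshold, , drop = FALSE]
  out <- out[order(-out$tau, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve for a score-based ranking
#'
#' Rank-based (Wilcoxon) AUROC of `scores` against binary `labels`; ties get
#' midranks, NA scores rank lowest. Used to benchmark planted-repressor
#' recovery.
#'
#' @param scores numeric vector (higher = more likely positive).
#' @param labels logical vector, TRUE for positives.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  scores[is.na(scores)] <- -Inf
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
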