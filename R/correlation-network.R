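#' Kendall rank correlation (tau-b, tie-corrected)
#'
#' Exact tie-corrected Kendall coefficient
#' tau_b = S / sqrt((n0 - Tx)(n0 - Ty)), with S the concordant-minus-
#' discordant pair count, n0 = n(n-1)/2, and Tx, Ty the numbers of pairs
#' tied in x resp. y. Suited to short stage-mean profiles where ties are
#' common; preferred over Pearson because it is insensitive to the large
#' postnatal expression jumps.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau in [-1, 1]; NA with a warning if either vector is constant.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 2) stop("need at least 2 observations")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  Tx <- sum(dx[up] == 0)
  Ty <- sum(dy[up] == 0)
  if (Tx == n0 || Ty == n0) {
    warning("zero variance: Kendall tau undefined")
    return(NA_real_)
  }
  S / sqrt((n0 - Tx) * (n0 - Ty))
}

#' Attach Kendall correlations to interactions
#'
#' For every interaction whose two partners have stage profiles, computes
#' the Kendall tau over the full stage series (`tau_full`) and over
#' embryonic stages only (`tau_dev`), and flags anti-correlation by strict
#' comparison of the mode-selected tau with `threshold`. Interactions with a
#' missing partner profile are skipped (counted in the message), since DE
#' sets and interaction resources only partially overlap.
#'
#' @param interactions data.frame with `mirna_id`, `gene_id` columns.
#' @param mirna_profiles,gene_profiles full-series stage-mean matrices
#'   (features x stages) from [stage_means()] with `dev_only = FALSE`.
#' @param threshold anti-correlation threshold (default -0.4, strict "<").
#' @param mode which tau drives `is_anticorrelated`: "dev" (embryonic
#'   stages only) or "full".
#' @return The interactions with `tau_full`, `tau_dev`,
#'   `is_anticorrelated` columns added (skipped rows removed).
#' @export
annotate_correlations <- function(interactions, mirna_profiles, gene_profiles,
                                  threshold = -0.4, mode = c("dev", "full")) {
  mode <- match.arg(mode)
  mirna_profiles <- unclass(mirna_profiles)
  gene_profiles <- unclass(gene_profiles)
  dev_cols <- dev_stages(colnames(mirna_profiles))
  have <- interactions$mirna_id %in% rownames(mirna_profiles) &
    interactions$gene_id %in% rownames(gene_profiles)
  if (any(!have))
    message(sprintf("skipped %d interactions lacking a partner profile",
                    sum(!have)))
  out <- interactions[have, , drop = FALSE]
  n <- nrow(out)
  tau_full <- tau_dev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mp <- mirna_profiles[out$mirna_id[i], ]
    gp <- gene_profiles[out$gene_id[i], ]
    tau_full[i] <- suppressWarnings(kendall_tau(mp, gp))
    tau_dev[i] <- suppressWarnings(kendall_tau(mp[dev_cols], gp[dev_cols]))
  }
  out$tau_full <- tau_full
  out$tau_dev <- tau_dev
  tau_sel <- if (mode == "dev") tau_dev else tau_full
  out$is_anticorrelated <- !is.na(tau_sel) & tau_sel < threshold
  rownames(out) <- NULL
  out
}

#' Cluster-level interaction count matrices
#'
#' Aggregates interactions to the cluster level: `M_all[i, j]` counts every
#' interaction between a miRNA in cluster i and a gene in cluster j;
#' `M_neg` counts the anti-correlated subset. Also reports the number of
#' distinct anti-correlated target genes per cluster pair. Interactions with
#' an unlabeled partner are skipped.
#'
#' @param correlated output of [annotate_correlations()].
#' @param mir_labels,gene_labels named integer vectors of hard cluster
#'   labels (e.g. `model$cluster`).
#' @return A `ClusterLinkMatrix` list: `M_all`, `M_neg`,
#'   `n_anticorr_targets` (matrices, miRNA clusters x gene clusters),
#'   `n_skipped`.
#' @export
build_link_matrices <- function(correlated, mir_labels, gene_labels) {
  cm <- max(1L, if (length(mir_labels)) max(mir_labels) else 1L)
  cg <- max(1L, if (length(gene_labels)) max(gene_labels) else 1L)
  M_all <- matrix(0L, cm, cg,
                  dimnames = list(mir_cluster = seq_len(cm),
                                  gene_cluster = seq_len(cg)))
  M_neg <- M_all
  n_anti_targets <- M_all
  have <- correlated$mirna_id %in% names(mir_labels) &
    correlated$gene_id %in% names(gene_labels)
  n_skipped <- sum(!have)
  if (n_skipped)
    message(sprintf("skipped %d interactions with unlabeled partner", n_skipped))
  sub <- correlated[have, , drop = FALSE]
  if (nrow(sub)) {
    i <- mir_labels[sub$mirna_id]
    j <- gene_labels[sub$gene_id]
    for (k in seq_len(nrow(sub))) {
      M_all[i[k], j[k]] <- M_all[i[k], j[k]] + 1L
      if (isTRUE(sub$is_anticorrelated[k]))
        M_neg[i[k], j[k]] <- M_neg[i[k], j[k]] + 1L
    }
    anti <- sub[isTRUE_vec(sub$is_anticorrelated), , drop = FALSE]
    if (nrow(anti)) {
      tab <- tapply(anti$gene_id,
                    list(factor(mir_labels[anti$mirna_id], seq_len(cm)),
                         factor(gene_labels[anti$gene_id], seq_len(cg))),
                    function(g) length(unique(g)))
      tab[is.na(tab)] <- 0L
      n_anti_targets[] <- tab
    }
  }
  structure(list(M_all = M_all, M_neg = M_neg,
                 n_anticorr_targets = n_anti_targets, n_skipped = n_skipped),
            class = "ClusterLinkMatrix")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Cluster pairs dominated by anti-correlated interactions
#'
#' A (miRNA cluster, gene cluster) pair is a dominant link when it has any
#' interactions and strictly more than `rule_fraction` of them are
#' anti-correlated.
#'
#' @param matrices a `ClusterLinkMatrix` from [build_link_matrices()].
#' @param rule_fraction dominance fraction (default 0.5, strict ">").
#' @return data.frame with mir_cluster, gene_cluster, M_all, M_neg, fraction.
#' @export
dominant_links <- function(matrices, rule_fraction = 0.5) {
  stopifnot(inherits(matrices, "ClusterLinkMatrix"))
  M_all <- matrices$M_all; M_neg <- matrices$M_neg
  idx <- which(M_all > 0 & M_neg / pmax(M_all, 1L) > rule_fraction,
               arr.ind = TRUE)
  data.frame(mir_cluster = as.integer(idx[, 1]),
             gene_cluster = as.integer(idx[, 2]),
             M_all = M_all[idx], M_neg = M_neg[idx],
             fraction = M_neg[idx] / M_all[idx], row.names = NULL)
}
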