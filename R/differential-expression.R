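#' Benjamini-Hochberg step-up adjustment
#'
#' Literal step-up procedure: order p ascending, compute p_(i) * m / i, take
#' cumulative minima from the largest rank down, clip at 1, and return in the
#' original order.
#'
#' @param p numeric vector of p values in [0,1] (NAs preserved).
#' @return Adjusted p values, same length and order as the input.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must be in [0,1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  out[ok] <- adj
  out
}

# Newton inversion of the trigamma function (psigamma deriv = 1), used by the
# method-of-moments prior df estimate. Monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the variance prior by moment matching on log sample variances
#'
#' Fits the scaled inverse-chi-square prior s^2 ~ s0^2 * d0 / chi^2_d0 to
#' per-feature sample variances by matching the mean and variance of
#' log(s_g^2) through digamma/trigamma identities. When the observed spread
#' of log variances does not exceed what the residual degrees of freedom
#' alone explain, the prior df is infinite (variances treated as common).
#'
#' @param s2 per-feature sample variances (positive).
#' @param df residual degrees of freedom (scalar or per-feature vector).
#' @param d0_cap prior df above this value is reported as `Inf`.
#' @return List with `d0` (prior df) and `s0_sq` (prior variance).
#' @export
estimate_variance_prior <- function(s2, df, d0_cap = 1e6) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(keep) < 2) stop("need at least 2 positive variances")
  s2k <- s2[keep]; dfk <- df[keep]
  z <- log(s2k)
  e <- z - digamma(dfk / 2) + log(dfk / 2)
  e_bar <- mean(e)
  n <- length(e)
  ev <- mean((e - e_bar)^2) * n / (n - 1) - mean(trigamma(dfk / 2))
  if (ev <= 0) {
    d0 <- Inf
    s0_sq <- exp(e_bar)
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    if (d0 > d0_cap) {
      d0 <- Inf
      s0_sq <- exp(e_bar)
    } else {
      s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  list(d0 = d0, s0_sq = s0_sq)
}

moderate_variances <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) rep_len(prior$s0_sq, length(s2))
  else (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
}

#' Moderated two-sample t test per feature
#'
#' Classical pooled two-sample t statistics with empirical-Bayes variance
#' shrinkage: per-feature pooled variances are shrunk toward a prior
#' (d0, s0^2) estimated by moment matching on log variances
#' ([estimate_variance_prior()]); the moderated t is referred to a
#' t distribution with d0 + d_g degrees of freedom. `prior_df = 0` recovers
#' the classical pooled t; `prior_df = Inf` uses the common variance s0^2
#' for every feature.
#'
#' @param em an [expression_matrix()] object.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2. The log2 fold change is mean(a) - mean(b).
#' @param contrast label stored in the result.
#' @param prior_df `NULL` (estimate), `0`, `Inf`, or a fixed value.
#' @return data.frame with columns feature_id, contrast, log2FC, t_mod,
#'   p_raw, plus attributes `d0`, `s0_sq`, `s_tilde_sq`.
#' @export
fit_moderated_t <- function(em, group_a, group_b, contrast = "a_vs_b",
                            prior_df = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  bad <- setdiff(c(group_a, group_b), colnames(em$values))
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  if (nrow(em$values) < 10)
    warning("fewer than 10 features: prior estimate may be unstable")
  xa <- em$values[, group_a, drop = FALSE]
  xb <- em$values[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  dg <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / dg
  lfc <- ma - mb
  moderated_result(lfc, s2, dg, sqrt(1 / na + 1 / nb),
                   rownames(em$values), contrast, prior_df)
}

# shared tail: shrink variances, form t, two-sided p
moderated_result <- function(lfc, s2, dg, se_scale, ids, contrast, prior_df) {
  s2f <- pmax(s2, 1e-12)  # guard exact-zero variances before taking logs
  prior <- if (is.null(prior_df)) {
    estimate_variance_prior(s2f, dg)
  } else if (prior_df == 0) {
    list(d0 = 0, s0_sq = mean(s2f))
  } else if (is.infinite(prior_df)) {
    p <- estimate_variance_prior(s2f, dg)
    list(d0 = Inf, s0_sq = p$s0_sq)
  } else {
    p <- estimate_variance_prior(s2f, dg)
    list(d0 = prior_df, s0_sq = p$s0_sq)
  }
  s_tilde_sq <- moderate_variances(s2f, dg, prior)
  t_mod <- lfc / (sqrt(s_tilde_sq) * se_scale)
  df_total <- if (is.infinite(prior$d0)) Inf else prior$d0 + dg
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(feature_id = ids, contrast = contrast, log2FC = lfc,
                    t_mod = t_mod, p_raw = p_raw, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- prior$d0
  attr(res, "s0_sq") <- prior$s0_sq
  attr(res, "s_tilde_sq") <- s_tilde_sq
  attr(res, "df_residual") <- dg
  res
}

#' Flag differentially expressed features
#'
#' A feature is differentially expressed in a contrast when its BH-adjusted
#' p value is at most `p_threshold` and its absolute log2 fold change is at
#' least `lfc_threshold` (defaults 1e-5 and 2, i.e. 4-fold).
#'
#' @param results data.frame from [fit_moderated_t()] with `p_adj` present
#'   (added here from `p_raw` if missing, BH within each contrast).
#' @param p_threshold adjusted-p cutoff (inclusive).
#' @param lfc_threshold absolute log2 fold-change cutoff (inclusive).
#' @return The input with columns `p_adj`, `is_DE` and `direction`
#'   ("up"/"down"/"ns").
#' @export
call_de <- function(results, p_threshold = 1e-5, lfc_threshold = 2) {
  if (is.null(results$p_adj)) {
    results$p_adj <- NA_real_
    for (ct in unique(results$contrast)) {
      idx <- results$contrast == ct
      results$p_adj[idx] <- adjust_bh(results$p_raw[idx])
    }
  }
  results$is_DE <- results$p_adj <= p_threshold &
    abs(results$log2FC) >= lfc_threshold
  results$direction <- ifelse(!results$is_DE, "ns",
                              ifelse(results$log2FC > 0, "up", "down"))
  results
}

#' Differential expression of every stage against a reference stage
#'
#' Fits one moderated-t contrast per non-reference stage (stage minus
#' reference), adjusts p values across features within each contrast, and
#' flags DE calls.
#'
#' @param em an [expression_matrix()] object.
#' @param reference_stage stage label used as the baseline.
#' @param p_threshold,lfc_threshold DE thresholds, see [call_de()].
#' @param prior_df see [fit_moderated_t()].
#' @return data.frame of per-feature, per-contrast results; contrast labels
#'   are `"<stage>_vs_<reference>"`.
#' @export
de_vs_reference <- function(em, reference_stage, p_threshold = 1e-5,
                            lfc_threshold = 2, prior_df = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!reference_stage %in% em$stage_levels)
    stop("unknown reference stage: ", reference_stage)
  ref_samples <- em$samples$sample_id[em$samples$stage == reference_stage]
  others <- setdiff(em$stage_levels, reference_stage)
  others <- others[others %in% em$samples$stage]
  res <- lapply(others, function(s) {
    grp <- em$samples$sample_id[em$samples$stage == s]
    r <- fit_moderated_t(em, grp, ref_samples,
                         contrast = paste0(s, "_vs_", reference_stage),
                         prior_df = prior_df)
    r$p_adj <- adjust_bh(r$p_raw)
    r
  })
  call_de(do.call(rbind, res), p_threshold, lfc_threshold)
}

#' Paired male-vs-female contrast across stages
#'
#' At each included stage the male minus female log2 difference forms one
#' paired observation per feature; a moderated one-sample t on these
#' differences gives the overall sex contrast (analogous to a classical
#' paired t test). Mixed-sex samples are ignored. Stages where sex is not
#' yet resolved are excluded by default.
#'
#' @param em an [expression_matrix()] object.
#' @param excluded_stages stages dropped before pairing.
#' @param prior_df see [fit_moderated_t()].
#' @return data.frame as from [fit_moderated_t()], contrast "M_vs_F";
#'   log2FC is the mean male-minus-female difference.
#' @export
paired_sex_contrast <- function(em, excluded_stages = c("E10.5", "E11.5", "E12.5"),
                                prior_df = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  stages <- setdiff(unique(em$samples$stage), excluded_stages)
  diffs <- vapply(stages, function(s) {
    midx <- which(em$samples$stage == s & em$samples$sex == "M")
    fidx <- which(em$samples$stage == s & em$samples$sex == "F")
    if (length(midx) != 1 || length(fidx) != 1)
      stop("stage without exactly one M and one F sample: ", s)
    em$values[, midx] - em$values[, fidx]
  }, numeric(nrow(em$values)))
  if (nrow(em$values) == 1L) diffs <- matrix(diffs, nrow = 1)
  k <- length(stages)
  if (k < 2) stop("need at least 2 paired stages")
  d_bar <- rowMeans(diffs)
  s2 <- apply(diffs, 1, stats::var)
  res <- moderated_result(d_bar, s2, k - 1, 1 / sqrt(k),
                          rownames(em$values), "M_vs_F", prior_df)
  res$p_adj <- adjust_bh(res$p_raw)
  res
}

#' Per-stage counts of sex-biased features
#'
#' Counts features whose male-vs-female mean log2 difference exceeds
#' `log2_threshold` in absolute value (strictly), split by direction.
#'
#' @param em an [expression_matrix()] object.
#' @param log2_threshold log2 difference threshold (default 1 = 2-fold).
#' @return data.frame with columns stage, n_up_male, n_down_male.
#' @export
sex_fold_change_counts <- function(em, log2_threshold = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  stages <- unique(em$samples$stage)
  rows <- lapply(stages, function(s) {
    midx <- which(em$samples$stage == s & em$samples$sex == "M")
    fidx <- which(em$samples$stage == s & em$samples$sex == "F")
    if (!length(midx) || !length(fidx)) return(NULL)
    d <- rowMeans(em$values[, midx, drop = FALSE]) -
      rowMeans(em$values[, fidx, drop = FALSE])
    data.frame(stage = s, n_up_male = sum(d > log2_threshold),
               n_down_male = sum(d < -log2_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(stage = character(0),
                                      n_up_male = integer(0),
                                      n_down_male = integer(0))
  out
}

#' Compare two DE id sets
#'
#' @param set_a,set_b character vectors of feature ids (pooled or per
#'   contrast, as the caller prefers).
#' @return List with `common`, `unique_to_a`, `unique_to_b`.
#' @export
compare_de_sets <- function(set_a, set_b) {
  list(common = intersect(set_a, set_b),
       unique_to_a = setdiff(set_a, set_b),
       unique_to_b = setdiff(set_b, set_a))
}

#' Up/down DE counts per contrast
#'
#' @param results a DE data.frame with `is_DE` and `direction` set.
#' @return data.frame with contrast, n_up, n_down and the up/down ratio
#'   (NA when nothing is downregulated).
#' @export
summarize_de_counts <- function(results) {
  cts <- unique(results$contrast)
  rows <- lapply(cts, function(ct) {
    sub <- results[results$contrast == ct, ]
    up <- sum(sub$direction == "up"); dn <- sum(sub$direction == "down")
    data.frame(contrast = ct, n_up = up, n_down = dn,
               ratio = if (dn > 0) up / dn else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(contrast = character(0), n_up = integer(0),
                                      n_down = integer(0), ratio = numeric(0))
  out
}
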