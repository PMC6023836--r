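test_that("adjust_bh matches the literal step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(0.2, 0.2)), c(0.2, 0.2))
  expect_equal(adjust_bh(0.05), 0.05)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_identical(adjust_bh(p), bh_oracle(p))
  }
})

make_groups <- function(n_feat = 50, na = 3, nb = 3, seed = 1,
                        sds = NULL) {
  set.seed(seed)
  if (is.null(sds)) sds <- sqrt(1 / rgamma(n_feat, shape = 4, rate = 4))
  vals <- t(sapply(seq_len(n_feat), function(g)
    rnorm(na + nb, mean = 8, sd = sds[g])))
  rownames(vals) <- sprintf("f%02d", seq_len(n_feat))
  stages <- c("E10.5", "young")
  em <- toy_matrix(vals, stages, reps = na)
  list(em = em,
       a = em$samples$sample_id[em$samples$stage == "E10.5"],
       b = em$samples$sample_id[em$samples$stage == "young"])
}

test_that("moderated t has the correct limiting behavior", {
  g <- make_groups(seed = 2)
  # prior df 0: classical pooled two-sample t
  res0 <- fit_moderated_t(g$em, g$a, g$b, prior_df = 0)
  classical <- vapply(rownames(g$em$values), function(f)
    unname(stats::t.test(g$em$values[f, g$a], g$em$values[f, g$b],
                         var.equal = TRUE)$statistic), numeric(1))
  expect_equal(res0$t_mod, unname(classical), tolerance = 1e-10)

  # prior df Inf: common variance s0^2 in every denominator
  resInf <- fit_moderated_t(g$em, g$a, g$b, prior_df = Inf)
  s0 <- attr(resInf, "s0_sq")
  expect_equal(resInf$t_mod,
               resInf$log2FC / (sqrt(s0) * sqrt(1 / 3 + 1 / 3)),
               tolerance = 1e-12)
})

test_that("estimated prior and statistics match the independent oracle", {
  g <- make_groups(n_feat = 50, seed = 7)
  res <- fit_moderated_t(g$em, g$a, g$b)
  orc <- modt_oracle(g$em$values[, g$a], g$em$values[, g$b])
  expect_equal(attr(res, "d0"), orc$d0, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), orc$s0_sq, tolerance = 1e-8)
  expect_equal(res$t_mod, orc$t_mod, tolerance = 1e-8)
  expect_equal(res$log2FC, orc$lfc, tolerance = 1e-12)
})

test_that("group swap negates effect sizes and preserves p values", {
  g <- make_groups(seed = 9)
  ab <- fit_moderated_t(g$em, g$a, g$b)
  ba <- fit_moderated_t(g$em, g$b, g$a)
  expect_equal(ab$log2FC, -ba$log2FC)
  expect_equal(ab$t_mod, -ba$t_mod)
  expect_equal(ab$p_raw, ba$p_raw)
})

test_that("group validation catches bad designs", {
  g <- make_groups()
  expect_error(fit_moderated_t(g$em, g$a, c(g$b, g$a[1])), "overlap")
  expect_error(fit_moderated_t(g$em, g$a[1], g$b), "at least 2")
})

test_that("call_de applies the conjunction of thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c"), contrast = "x",
                    log2FC = c(2.5, -1.9, 3.0), t_mod = 0,
                    p_raw = c(1e-6, 1e-6, 2e-5),
                    p_adj = c(1e-6, 1e-6, 2e-5))
  out <- call_de(res)
  expect_equal(out$is_DE, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("up", "ns", "ns"))
})

test_that("de_vs_reference builds one contrast per non-reference stage", {
  ds <- generate_dataset(small_config(seed = 4))
  res <- de_vs_reference(ds$genes, "young")
  expect_length(unique(res$contrast), 11)
  expect_false(any(grepl("^young_vs", res$contrast)))

  res2 <- de_vs_reference(ds$genes, "E19.5")
  expect_false(any(grepl("^E19.5_vs", res2$contrast)))
  expect_length(unique(res2$contrast), 11)

  expect_error(de_vs_reference(ds$genes, "E99"), "unknown reference")
})

test_that("a single planted fold change is the only DE call", {
  stages <- default_stages()
  n_samp <- length(stages) * 3
  set.seed(13)
  vals <- matrix(8 + rnorm(20 * n_samp, 0, 0.05), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  em <- toy_matrix(vals, stages, reps = 3)
  idx <- em$samples$stage == "E10.5"
  em$values["g05", idx] <- em$values["g05", idx] + 4  # 16-fold at E10.5
  res <- de_vs_reference(em, "young")
  hits <- res[res$is_DE, ]
  expect_equal(hits$feature_id, "g05")
  expect_equal(hits$contrast, "E10.5_vs_young")
})

sex_matrix <- function(n_feat = 30, seed = 21, shift_feature = NULL,
                       shift = 0) {
  stages <- default_stages()
  set.seed(seed)
  sheet <- do.call(rbind, lapply(stages, function(s) data.frame(
    sample_id = paste0(s, "_r", 1:3), stage = s,
    sex = if (s %in% c("E10.5", "E11.5")) rep("mixed", 3)
          else c("F", "M", "mixed"),
    replicate = 1:3)))
  vals <- matrix(8 + rnorm(n_feat * nrow(sheet), 0, 0.3), n_feat,
                 dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                                 sheet$sample_id))
  if (!is.null(shift_feature)) {
    midx <- sheet$sex == "M"
    vals[shift_feature, midx] <- vals[shift_feature, midx] + shift
  }
  expression_matrix(vals, sheet, "gene", stages)
}

test_that("paired sex contrast estimates the male-female effect", {
  em <- sex_matrix()
  # make M and F columns identical
  em2 <- em
  for (s in unique(em$samples$stage)) {
    mi <- which(em$samples$stage == s & em$samples$sex == "M")
    fi <- which(em$samples$stage == s & em$samples$sex == "F")
    if (length(mi)) em2$values[, mi] <- em2$values[, fi]
  }
  res0 <- paired_sex_contrast(em2)
  expect_true(all(res0$log2FC == 0))

  shifted <- sex_matrix(shift_feature = "f03", shift = 1.25)
  res <- paired_sex_contrast(shifted)
  expect_equal(res$log2FC[res$feature_id == "f03"], 1.25, tolerance = 0.3)

  # d0 = 0 reduces to the classical paired t test
  res_classical <- paired_sex_contrast(shifted, prior_df = 0)
  stages_used <- setdiff(unique(shifted$samples$stage),
                         c("E10.5", "E11.5", "E12.5"))
  f <- "f07"
  d <- vapply(stages_used, function(s) {
    mi <- which(shifted$samples$stage == s & shifted$samples$sex == "M")
    fi <- which(shifted$samples$stage == s & shifted$samples$sex == "F")
    shifted$values[f, mi] - shifted$values[f, fi]
  }, numeric(1))
  tt <- stats::t.test(d)
  expect_equal(res_classical$t_mod[res_classical$feature_id == f],
               unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res_classical$p_raw[res_classical$feature_id == f],
               tt$p.value, tolerance = 1e-10)
})

test_that("sex fold-change counts use a strict threshold", {
  em <- sex_matrix(seed = 5)
  em$values[] <- 8  # no differences anywhere
  base <- sex_fold_change_counts(em)
  expect_true(all(base$n_up_male == 0) && all(base$n_down_male == 0))

  mi <- which(em$samples$stage == "E14.5" & em$samples$sex == "M")
  em$values["f01", mi] <- em$values["f01", mi] + 1.5
  one <- sex_fold_change_counts(em)
  expect_equal(one$n_up_male[one$stage == "E14.5"], 1)
  expect_equal(sum(one$n_up_male), 1)

  em$values["f01", mi] <- 8 + 1.0  # exactly at the threshold: not counted
  at <- sex_fold_change_counts(em)
  expect_equal(sum(at$n_up_male), 0)
})

test_that("compare_de_sets performs set algebra", {
  out <- compare_de_sets(c("x", "y"), c("y", "z"))
  expect_equal(out, list(common = "y", unique_to_a = "x", unique_to_b = "z"))
  same <- compare_de_sets(c("a", "b"), c("a", "b"))
  expect_length(same$unique_to_a, 0)
  disj <- compare_de_sets("a", "b")
  expect_length(disj$common, 0)
})

test_that("summarize_de_counts reports up/down ratios", {
  res <- data.frame(feature_id = sprintf("f%02d", 1:14),
                    contrast = "c1",
                    log2FC = c(rep(3, 10), rep(-3, 4)),
                    t_mod = 0, p_raw = 1e-9, p_adj = 1e-9)
  out <- summarize_de_counts(call_de(res))
  expect_equal(out$n_up, 10)
  expect_equal(out$n_down, 4)
  expect_equal(out$ratio, 2.5)

  res$log2FC <- abs(res$log2FC)
  out2 <- summarize_de_counts(call_de(res))
  expect_true(is.na(out2$ratio))
})
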