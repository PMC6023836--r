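#' Configuration for the synthetic paired time-course generator
#'
#' Describes a study design of paired gene/miRNA expression time courses over
#' a developmental series plus two mature stages, with archetypal temporal
#' profiles, planted repressive miRNA-target interactions among decoys,
#' additive Gaussian noise on the log2 scale, and pseudo target-prediction
#' resources with per-resource score distributions.
#'
#' The defaults emulate a murine heart development design: 12 stages (E10.5
#' to E19.5 daily, then young and old adult), 3 replicates per stage with one
#' female, one male and one mixed-sex replicate from E12.5 onward (mixed only
#' before, when sex differentiation is incomplete).
#'
#' @param n_genes,n_mirnas feature counts.
#' @param stages ordered stage labels; labels starting with "E" are embryonic.
#' @param n_replicates_per_stage replicates per stage (default 3).
#' @param archetype_mix named proportions over the five archetypes
#'   (must sum to 1).
#' @param n_planted_repressors number of miRNAs given repressed targets.
#' @param targets_per_repressor planted targets per repressor.
#' @param repression_strength in [0,1]; 1 means the target profile is a
#'   perfectly anti-monotone affine image of its miRNA profile.
#' @param decoy_interactions number of random miRNA-gene interaction rows
#'   added with independently drawn profiles (the negative class). The
#'   default (~3 extra interactions per miRNA) is calibrated so that planted
#'   repressors exhibit anti-correlated-target percentages around 70-85%,
#'   the range real studies report for their strongest regulators; much
#'   denser decoy sets dilute every miRNA's percentage toward the chance
#'   anti-correlation rate.
#' @param noise_sd replicate-level Gaussian noise SD, log2 units.
#' @param profile_jitter_sd SD (log2 units) of a smooth per-feature
#'   random-walk component added to each archetype profile, emulating the
#'   within-archetype diversity of real temporal profiles; planted targets
#'   inherit their miRNA's jitter through the repression mixture.
#' @param baseline_mean,baseline_sd per-feature baseline log2 intensity.
#' @param amplitude_range range of embryonic effect amplitudes (log2 units).
#' @param mature_effect_ratio mature-stage effect sizes are this multiple of
#'   embryonic step sizes (postnatal changes dominate the real data).
#' @param n_sex_specific number of sex-specific genes (female-only or
#'   male-only expression).
#' @param frac_targets_heart_dev,frac_targets_tx_regulator fraction of
#'   planted targets annotated with each category.
#' @param background_annotation_rate annotation rate among non-planted genes.
#' @param resources named list of pseudo-resources; each entry is a list with
#'   `evidence` ("predicted"/"experimental"), `direction` ("higher"/"lower"
#'   is better; predicted only) and `score_range` (numeric length 2).
#' @param seed integer RNG seed.
#' @return A validated `SyntheticConfig` object (list).
#' @export
synthetic_config <- function(n_genes = 500L,
                             n_mirnas = 200L,
                             stages = default_stages(),
                             n_replicates_per_stage = 3L,
                             archetype_mix = c(monotone_down = 0.20,
                                               monotone_up = 0.30,
                                               transient_peak = 0.15,
                                               postnatal_switch = 0.20,
                                               flat = 0.15),
                             n_planted_repressors = 30L,
                             targets_per_repressor = 5L,
                             repression_strength = 0.9,
                             decoy_interactions = 600L,
                             noise_sd = 0.3,
                             profile_jitter_sd = 0.75,
                             baseline_mean = 9,
                             baseline_sd = 0.5,
                             amplitude_range = c(3, 5),
                             mature_effect_ratio = 2,
                             n_sex_specific = 3L,
                             frac_targets_heart_dev = 0.8,
                             frac_targets_tx_regulator = 0.5,
                             background_annotation_rate = 0.05,
                             resources = default_resources(),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              stages = stages,
              n_replicates_per_stage = as.integer(n_replicates_per_stage),
              archetype_mix = archetype_mix,
              n_planted_repressors = as.integer(n_planted_repressors),
              targets_per_repressor = as.integer(targets_per_repressor),
              repression_strength = repression_strength,
              decoy_interactions = as.integer(decoy_interactions),
              noise_sd = noise_sd, profile_jitter_sd = profile_jitter_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, amplitude_range = amplitude_range,
              mature_effect_ratio = mature_effect_ratio,
              n_sex_specific = as.integer(n_sex_specific),
              frac_targets_heart_dev = frac_targets_heart_dev,
              frac_targets_tx_regulator = frac_targets_tx_regulator,
              background_annotation_rate = background_annotation_rate,
              resources = resources, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "SyntheticConfig")
}

#' Default stage labels: E10.5..E19.5 daily plus young and old adult
#' @return Character vector of 12 stage labels.
#' @export
default_stages <- function() {
  c(paste0("E", sprintf("%.1f", seq(10.5, 19.5, by = 1))), "young", "old")
}

#' Default pseudo-resources for interaction scores
#'
#' Three predicted resources (two higher-is-better in different score ranges,
#' one lower-is-better mimicking binding-energy scores) and one experimental
#' resource without scores.
#' @return Named list of resource descriptors.
#' @export
default_resources <- function() {
  list(predictA = list(evidence = "predicted", direction = "higher",
                       score_range = c(50, 100)),
       predictB = list(evidence = "predicted", direction = "higher",
                       score_range = c(0, 1)),
       predictC = list(evidence = "predicted", direction = "lower",
                       score_range = c(-30, 0)),
       validated = list(evidence = "experimental"))
}

validate_synthetic_config <- function(cfg) {
  archetypes <- c("monotone_down", "monotone_up", "transient_peak",
                  "postnatal_switch", "flat")
  if (!setequal(names(cfg$archetype_mix), archetypes))
    stop("archetype_mix must be named over: ", paste(archetypes, collapse = ", "))
  if (abs(sum(cfg$archetype_mix) - 1) > 1e-9)
    stop("archetype_mix proportions must sum to 1")
  counts <- c(cfg$n_genes, cfg$n_mirnas, cfg$n_replicates_per_stage,
              cfg$n_planted_repressors, cfg$targets_per_repressor)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$n_planted_repressors > cfg$n_mirnas)
    stop("n_planted_repressors must not exceed n_mirnas")
  if (cfg$n_planted_repressors * cfg$targets_per_repressor > cfg$n_genes)
    stop("planted targets exceed n_genes")
  if (cfg$repression_strength < 0 || cfg$repression_strength > 1)
    stop("repression_strength must be in [0,1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(dev_stages(cfg$stages)) < 3)
    stop("need at least 3 embryonic stages")
  invisible(cfg)
}

archetype_names <- function() {
  c("monotone_down", "monotone_up", "transient_peak", "postnatal_switch", "flat")
}

#' Build one archetypal stage profile
#'
#' The archetypes capture the temporal motifs seen in developmental heart
#' expression: monotone down/up-regulation over embryonic stages, a transient
#' peak at an interior embryonic stage, a postnatal switch (near-constant
#' embryonically, elevated after birth), and flat. Mature-stage changes are
#' scaled by `mature_ratio` relative to embryonic per-stage steps.
#'
#' @param archetype one of `"monotone_down"`, `"monotone_up"`,
#'   `"transient_peak"`, `"postnatal_switch"`, `"flat"`.
#' @param stages ordered stage labels ("E"-prefixed = embryonic).
#' @param amplitude log2-unit effect size over the embryonic series (for
#'   `postnatal_switch`, the minimum mature elevation).
#' @param mature_ratio multiplier on the embryonic per-stage step applied to
#'   mature stages (monotone archetypes keep their trend after birth).
#' @param peak_at optional interior embryonic index for the transient peak;
#'   default the middle embryonic stage.
#' @return Named numeric vector, one value per stage (centered at 0).
#' @export
make_archetype_profile <- function(archetype, stages = default_stages(),
                                   amplitude = 4, mature_ratio = 2,
                                   peak_at = NULL) {
  if (!archetype %in% archetype_names())
    stop("unknown archetype '", archetype, "'; valid: ",
         paste(archetype_names(), collapse = ", "))
  emb <- dev_stages(stages)
  n_emb <- length(emb)
  n_mat <- length(stages) - n_emb
  step <- if (n_emb > 1) amplitude / (n_emb - 1) else amplitude
  prof <- switch(archetype,
    flat = rep(0, length(stages)),
    monotone_down = c(seq(amplitude, 0, length.out = n_emb),
                      if (n_mat > 0) -mature_ratio * step * seq_len(n_mat)),
    monotone_up = c(seq(0, amplitude, length.out = n_emb),
                    if (n_mat > 0) amplitude + mature_ratio * step * seq_len(n_mat)),
    transient_peak = {
      if (is.null(peak_at)) peak_at <- ceiling(n_emb / 2)
      if (peak_at <= 1 || peak_at >= n_emb)
        stop("transient peak must be at an interior embryonic stage")
      up <- seq(0, amplitude, length.out = peak_at)
      down <- seq(amplitude, 0, length.out = n_emb - peak_at + 1)[-1]
      c(up, down, rep(0, n_mat))
    },
    postnatal_switch = c(rep(0, n_emb),
                         rep(amplitude * max(1, mature_ratio / 2), n_mat)))
  prof <- prof - mean(prof)
  names(prof) <- stages
  prof
}

#' Derive a repressed target profile from a miRNA profile
#'
#' Realizes the post-transcriptional repression assumption: the target's
#' temporal profile is a mixture of an independent archetype draw and the
#' negated (anti-monotone) miRNA profile. With `strength = 1` and no noise
#' the target is a strictly decreasing affine function of the miRNA profile,
#' so the Kendall correlation over stages is exactly -1.
#'
#' @param mirna_profile numeric stage profile of the repressing miRNA.
#' @param strength mixing weight in [0,1] of the repressive component.
#' @param noise_sd SD of additive Gaussian noise on the profile (log2 units).
#' @param independent_profile profile used for the non-repressed component;
#'   defaults to a random archetype draw at the same amplitude.
#' @return Numeric stage profile of the target gene (centered).
#' @export
plant_repression <- function(mirna_profile, strength, noise_sd = 0,
                             independent_profile = NULL) {
  if (strength < 0 || strength > 1) stop("strength must be in [0,1]")
  stages <- names(mirna_profile)
  if (is.null(independent_profile)) {
    arch <- sample(setdiff(archetype_names(), "flat"), 1L)
    amp <- stats::runif(1, 3, 5)
    independent_profile <- make_archetype_profile(arch, stages, amp)
  }
  scale <- if (stats::sd(mirna_profile) > 0) 1 else 0
  repressed <- -scale * (mirna_profile - mean(mirna_profile))
  prof <- (1 - strength) * independent_profile + strength * repressed
  prof <- prof + stats::rnorm(length(prof), 0, noise_sd)
  names(prof) <- stages
  prof
}

#' Generate a paired synthetic dataset with planted regulatory structure
#'
#' Produces gene and miRNA [expression_matrix()] objects, an interaction
#' table (planted repressive pairs plus random decoys, with per-resource
#' scores), a gene annotation table (heart_dev / tx_regulator flags), and a
#' ground-truth object for benchmarking. Identical configs (including seed)
#' reproduce identical outputs.
#'
#' @param config a [synthetic_config()] object.
#' @return List with `genes`, `mirnas` (ExpressionMatrix), `interactions`
#'   (data.frame: mirna_id, gene_id, resource, evidence, score),
#'   `annotations` (data.frame: gene_id, category), and `truth`
#'   (list: planted_interactions, archetype_of_feature, sex_specific_genes,
#'   expressed_flags).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  stages <- config$stages
  n_stage <- length(stages)
  reps <- config$n_replicates_per_stage

  samples <- make_sample_sheet(stages, reps)
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  mir_ids <- sprintf("miR-%03d", seq_len(config$n_mirnas))

  draw_archetype <- function(n)
    sample(names(config$archetype_mix), n, replace = TRUE,
           prob = config$archetype_mix)
  draw_profile <- function(arch) {
    amp <- stats::runif(1, config$amplitude_range[1], config$amplitude_range[2])
    peak <- NULL
    n_emb <- length(dev_stages(stages))
    if (arch == "transient_peak") peak <- sample(2:(n_emb - 1), 1)
    prof <- make_archetype_profile(arch, stages, amp,
                                   config$mature_effect_ratio, peak)
    if (config$profile_jitter_sd > 0) {
      # smooth per-feature deviation from the archetype shape
      jit <- cumsum(stats::rnorm(n_stage))
      jit <- jit - mean(jit)
      s <- stats::sd(jit)
      if (s > 0) prof <- prof + jit * (config$profile_jitter_sd / s)
    }
    prof
  }

  gene_arch <- stats::setNames(draw_archetype(config$n_genes), gene_ids)
  mir_arch <- stats::setNames(draw_archetype(config$n_mirnas), mir_ids)

  # planted repressors must vary over the developmental window, else no
  # embryonic anti-correlation exists to recover: flat and postnatal-only
  # archetypes are reassigned to a developmental one
  dev_archetypes <- c("monotone_down", "monotone_up", "transient_peak")
  repressors <- sample(mir_ids, config$n_planted_repressors)
  static_rep <- repressors[!mir_arch[repressors] %in% dev_archetypes]
  if (length(static_rep))
    mir_arch[static_rep] <- sample(dev_archetypes, length(static_rep),
                                   replace = TRUE)

  mir_profiles <- t(vapply(mir_ids, function(id) draw_profile(mir_arch[id]),
                           numeric(n_stage)))
  gene_profiles <- t(vapply(gene_ids, function(id) draw_profile(gene_arch[id]),
                            numeric(n_stage)))

  # assign planted targets (disjoint across repressors) and overwrite their
  # profiles with the repressed mixture
  n_planted <- config$n_planted_repressors * config$targets_per_repressor
  planted_genes <- sample(gene_ids, n_planted)
  planted <- data.frame(
    mirna_id = rep(repressors, each = config$targets_per_repressor),
    gene_id = planted_genes,
    strength = config$repression_strength,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(planted))) {
    g <- planted$gene_id[i]
    gene_profiles[g, ] <- plant_repression(
      mir_profiles[planted$mirna_id[i], ], config$repression_strength,
      noise_sd = 0)
    gene_arch[g] <- "planted_target"
  }

  baselines_g <- stats::rnorm(config$n_genes, config$baseline_mean,
                              config$baseline_sd)
  baselines_m <- stats::rnorm(config$n_mirnas, config$baseline_mean,
                              config$baseline_sd)

  expand <- function(profiles, baselines) {
    mu <- sweep(profiles[, samples$stage, drop = FALSE], 1, baselines, "+")
    noise <- matrix(stats::rnorm(length(mu), 0, config$noise_sd), nrow(mu))
    vals <- mu + noise
    colnames(vals) <- samples$sample_id
    vals
  }
  gene_vals <- expand(gene_profiles, baselines_g)
  mir_vals <- expand(mir_profiles, baselines_m)

  # sex-specific genes: expressed in one sex only (mixed gets half effect)
  sex_genes <- character(0)
  if (config$n_sex_specific > 0) {
    candidates <- setdiff(gene_ids, planted$gene_id)
    sex_genes <- sample(candidates, min(config$n_sex_specific, length(candidates)))
    for (i in seq_along(sex_genes)) {
      up_sex <- if (i %% 2 == 0) "M" else "F"
      eff <- ifelse(samples$sex == up_sex, 3,
                    ifelse(samples$sex == "mixed", 1.5, 0))
      gene_vals[sex_genes[i], ] <- gene_vals[sex_genes[i], ] + eff
    }
  }

  genes <- expression_matrix(gene_vals, samples, "gene", stages)
  mirnas <- expression_matrix(mir_vals, samples, "miRNA", stages)

  interactions <- build_interaction_table(planted, mir_ids, gene_ids, config)
  annotations <- build_annotation_table(planted, gene_ids, config)

  thresh <- 5
  expressed_flags <- c(
    apply(stage_means(genes), 1, max) > thresh,
    apply(stage_means(mirnas), 1, max) > thresh)

  truth <- list(planted_interactions = planted,
                archetype_of_feature = c(gene_arch, mir_arch),
                planted_repressors = repressors,
                sex_specific_genes = sex_genes,
                expressed_flags = expressed_flags)
  list(genes = genes, mirnas = mirnas, interactions = interactions,
       annotations = annotations, truth = truth)
}

make_sample_sheet <- function(stages, reps) {
  # one F, one M, one mixed from E12.5 onward; mixed-only at E10.5/E11.5
  emb <- dev_stages(stages)
  pre_sex <- emb[seq_len(min(2, length(emb)))]
  rows <- lapply(stages, function(s) {
    sex <- if (s %in% pre_sex) rep("mixed", reps)
           else c("F", "M", rep("mixed", max(0, reps - 2)))[seq_len(reps)]
    data.frame(sample_id = sprintf("%s_r%d", s, seq_len(reps)),
               stage = s, sex = sex, replicate = seq_len(reps),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

build_interaction_table <- function(planted, mir_ids, gene_ids, config) {
  planted_keys <- paste(planted$mirna_id, planted$gene_id)
  n_decoy <- config$decoy_interactions
  decoy_m <- sample(mir_ids, n_decoy * 2, replace = TRUE)
  decoy_g <- sample(gene_ids, n_decoy * 2, replace = TRUE)
  keys <- paste(decoy_m, decoy_g)
  ok <- !(keys %in% planted_keys) & !duplicated(keys)
  decoy <- data.frame(mirna_id = decoy_m[ok], gene_id = decoy_g[ok],
                      stringsAsFactors = FALSE)[seq_len(min(n_decoy, sum(ok))), ]
  all_pairs <- rbind(planted[, c("mirna_id", "gene_id")], decoy)
  all_pairs$is_planted <- rep(c(TRUE, FALSE), c(nrow(planted), nrow(decoy)))

  res_names <- names(config$resources)
  rows <- lapply(seq_len(nrow(all_pairs)), function(i) {
    # planted pairs get 1-2 supporting resources; decoys 1
    n_res <- if (all_pairs$is_planted[i]) sample(1:2, 1) else 1L
    picked <- sample(res_names, n_res)
    data.frame(mirna_id = all_pairs$mirna_id[i], gene_id = all_pairs$gene_id[i],
               resource = picked, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$evidence <- vapply(tab$resource,
                         function(r) config$resources[[r]]$evidence, "")
  tab$is_planted <- paste(tab$mirna_id, tab$gene_id) %in% planted_keys
  # true targets score well: planted pairs draw from the top 30% of each
  # resource's score range, decoys from the whole range
  tab$score <- NA_real_
  for (r in res_names) {
    spec <- config$resources[[r]]
    idx <- which(tab$resource == r)
    if (spec$evidence == "predicted" && length(idx)) {
      u <- ifelse(tab$is_planted[idx],
                  stats::runif(length(idx), 0.7, 1),
                  stats::runif(length(idx), 0, 1))
      lo <- spec$score_range[1]; hi <- spec$score_range[2]
      tab$score[idx] <- if (spec$direction == "higher") lo + u * (hi - lo)
                        else hi - u * (hi - lo)
    }
  }
  tab$is_planted <- NULL
  rownames(tab) <- NULL
  tab
}

build_annotation_table <- function(planted, gene_ids, config) {
  targets <- unique(planted$gene_id)
  others <- setdiff(gene_ids, targets)
  pick <- function(x, frac) x[stats::runif(length(x)) < frac]
  heart <- c(pick(targets, config$frac_targets_heart_dev),
             pick(others, config$background_annotation_rate))
  txreg <- c(pick(targets, config$frac_targets_tx_regulator),
             pick(others, config$background_annotation_rate))
  ann <- rbind(
    if (length(heart)) data.frame(gene_id = heart, category = "heart_dev",
                                  stringsAsFactors = FALSE),
    if (length(txreg)) data.frame(gene_id = txreg, category = "tx_regulator",
                                  stringsAsFactors = FALSE))
  if (is.null(ann)) ann <- data.frame(gene_id = character(0),
                                      category = character(0))
  ann[order(ann$gene_id, ann$category), , drop = FALSE]
}

#' Write a generated dataset to a directory of TSV files
#'
#' Emits the formats consumed by the rest of the pipeline: expression
#' matrices + sample sheet, per-resource interaction files, annotation table,
#' and truth tables.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$genes, file.path(dir, "genes.tsv"),
                   file.path(dir, "samples.tsv"))
  write_expression(dataset$mirnas, file.path(dir, "mirnas.tsv"))
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  for (r in unique(dataset$interactions$resource)) {
    sub <- dataset$interactions[dataset$interactions$resource == r,
                                c("mirna_id", "gene_id", "score")]
    wt(sub, paste0("interactions_", r, ".tsv"))
  }
  wt(dataset$annotations, "annotations.tsv")
  wt(dataset$truth$planted_interactions, "truth_planted.tsv")
  arch <- dataset$truth$archetype_of_feature
  wt(data.frame(feature_id = names(arch), archetype = unname(arch)),
     "truth_archetypes.tsv")
  invisible(dir)
}
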