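# Shared fixture builders. Everything is generated in code at test time.

# paste0 maps zero-length inputs to "", so id sequences need a guard
gids <- function(prefix, idx) {
  if (!length(idx)) character(0) else paste0(prefix, idx)
}

# a reduced synthetic design that keeps unit tests fast
small_config <- function(seed = 1L, ...) {
  base <- list(n_genes = 120L, n_mirnas = 40L, n_planted_repressors = 10L,
               targets_per_repressor = 3L, decoy_interactions = 80L,
               seed = seed)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

# tiny expression matrix with explicit values: f features x (stages x reps)
toy_matrix <- function(values, stages, reps = 2, feature_kind = "gene",
                       sexes = NULL) {
  n_samp <- length(stages) * reps
  stopifnot(ncol(values) == n_samp)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  sheet <- data.frame(
    sample_id = paste0(rep(stages, each = reps), "_r", rep(seq_len(reps),
                                                           length(stages))),
    stage = rep(stages, each = reps),
    sex = if (is.null(sexes)) "mixed" else sexes,
    replicate = rep(seq_len(reps), length(stages)))
  colnames(values) <- sheet$sample_id
  expression_matrix(values, sheet, feature_kind, stages)
}

# noisy copies of archetype profiles, standardized, with truth labels
archetype_panel <- function(archs, n_each, noise_sd, stages = default_stages(),
                            amplitude = 4) {
  X <- do.call(rbind, lapply(seq_along(archs), function(i) {
    base <- make_archetype_profile(archs[i], stages, amplitude)
    t(replicate(n_each, base + rnorm(length(base), 0, noise_sd)))
  }))
  rownames(X) <- sprintf("f%03d", seq_len(nrow(X)))
  list(X = standardize_profiles(X)$profiles,
       truth = rep(seq_along(archs), each = n_each))
}
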