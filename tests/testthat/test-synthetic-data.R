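test_that("archetype profiles have their defining shapes", {
  stages <- default_stages()
  emb <- dev_stages(stages)

  flat <- make_archetype_profile("flat", stages, amplitude = 7)
  expect_true(all(flat == flat[1]))

  down <- make_archetype_profile("monotone_down", stages, amplitude = 4)
  expect_true(all(diff(down[emb]) < 0))
  expect_equal(unname(down[emb[1]] - down[emb[length(emb)]]), 4)

  up <- make_archetype_profile("monotone_up", stages, amplitude = 4)
  expect_true(all(diff(up[emb]) > 0))

  peak <- make_archetype_profile("transient_peak", stages, amplitude = 3)
  amax <- which.max(peak)
  expect_gt(amax, 1)
  expect_lt(amax, length(emb))
  expect_equal(sum(peak == max(peak)), 1)

  sw <- make_archetype_profile("postnatal_switch", stages, amplitude = 3)
  expect_true(all(sw[emb] == sw[emb[1]]))
  expect_true(all(sw[c("young", "old")] - sw[emb[1]] >= 3))

  expect_error(make_archetype_profile("sawtooth", stages),
               "monotone_down.*flat")
})

test_that("plant_repression realizes anti-monotone repression", {
  stages <- default_stages()
  mir <- make_archetype_profile("monotone_up", stages, amplitude = 4)

  tgt <- plant_repression(mir, strength = 1, noise_sd = 0)
  expect_true(all(diff(tgt[dev_stages(stages)]) < 0))
  expect_equal(kendall_tau(mir, tgt), -1)

  indep <- make_archetype_profile("transient_peak", stages, amplitude = 3)
  tgt0 <- plant_repression(mir, strength = 0, noise_sd = 0,
                           independent_profile = indep)
  expect_equal(unname(tgt0), unname(indep))

  set.seed(7)
  a <- plant_repression(mir, 0.8, 0.2)
  set.seed(7)
  b <- plant_repression(mir, 0.8, 0.2)
  expect_identical(a, b)

  expect_error(plant_repression(mir, strength = 1.2), "\\[0,1\\]")
})

test_that("generate_dataset honours the configured design", {
  cfg <- small_config(seed = 3)
  ds <- generate_dataset(cfg)

  n_samp <- length(cfg$stages) * cfg$n_replicates_per_stage
  expect_equal(dim(ds$genes), c(120, n_samp))
  expect_equal(dim(ds$mirnas), c(40, n_samp))

  # sex scheme: mixed-only before E12.5, F/M/mixed from E12.5 on
  sheet <- ds$genes$samples
  pre <- sheet[sheet$stage %in% c("E10.5", "E11.5"), ]
  expect_true(all(pre$sex == "mixed"))
  later <- sheet[sheet$stage == "E15.5", ]
  expect_setequal(later$sex, c("F", "M", "mixed"))

  # planted interactions all present in the emitted table
  key <- function(d) paste(d$mirna_id, d$gene_id)
  expect_equal(nrow(ds$truth$planted_interactions), 30)
  expect_true(all(key(ds$truth$planted_interactions) %in% key(ds$interactions)))

  # every feature has an archetype assigned
  expect_setequal(names(ds$truth$archetype_of_feature),
                  c(rownames(ds$genes$values), rownames(ds$mirnas$values)))
})

test_that("identical config reproduces identical outputs", {
  a <- generate_dataset(small_config(seed = 11))
  b <- generate_dataset(small_config(seed = 11))
  expect_identical(a$genes$values, b$genes$values)
  expect_identical(a$mirnas$values, b$mirnas$values)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$annotations, b$annotations)

  d <- generate_dataset(small_config(seed = 12))
  expect_false(identical(a$genes$values, d$genes$values))
})

test_that("noise-free full-strength planting gives tau exactly -1", {
  cfg <- small_config(seed = 5, noise_sd = 0, repression_strength = 1)
  ds <- generate_dataset(cfg)
  gm <- stage_means(ds$genes)
  mm <- stage_means(ds$mirnas)
  pl <- ds$truth$planted_interactions
  taus <- vapply(seq_len(nrow(pl)), function(i)
    kendall_tau(mm[pl$mirna_id[i], ], gm[pl$gene_id[i], ]), numeric(1))
  expect_true(all(taus == -1))
})

test_that("planted interactions survive the expression filter", {
  ds <- generate_dataset(small_config(seed = 2))
  fg <- filter_expressed(ds$genes, 5)
  fm <- filter_expressed(ds$mirnas, 5)
  pl <- ds$truth$planted_interactions
  expect_true(all(pl$gene_id %in% rownames(fg$matrix$values)))
  expect_true(all(pl$mirna_id %in% rownames(fm$matrix$values)))
})

test_that("archetype frequencies follow the configured mix", {
  # pooled chi-square over 20 seeded runs, on features whose archetype is a
  # free multinomial draw (planted repressors/targets are constrained)
  mix <- c(monotone_down = 0.2, monotone_up = 0.3, transient_peak = 0.15,
           postnatal_switch = 0.2, flat = 0.15)
  counts <- stats::setNames(rep(0, 5), names(mix))
  for (s in 1:20) {
    ds <- generate_dataset(small_config(seed = 100 + s))
    arch <- ds$truth$archetype_of_feature
    pl <- ds$truth$planted_interactions
    free <- setdiff(rownames(ds$genes$values), pl$gene_id)
    tab <- table(factor(arch[free], levels = names(mix)))
    counts <- counts + as.numeric(tab)
  }
  p <- stats::chisq.test(counts, p = mix[names(mix)])$p.value
  expect_gt(p, 0.01)
})

test_that("synthetic config validation rejects bad designs", {
  expect_error(small_config(archetype_mix = c(monotone_down = 0.5,
                                              monotone_up = 0.6,
                                              transient_peak = 0,
                                              postnatal_switch = 0,
                                              flat = 0)), "sum to 1")
  expect_error(synthetic_config(n_mirnas = 5, n_planted_repressors = 10),
               "exceed")
  expect_error(small_config(repression_strength = 2), "\\[0,1\\]")
  expect_error(small_config(n_genes = -1), "positive")
})

test_that("write_dataset emits readable TSVs", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_config(seed = 8))
  write_dataset(ds, dir)
  back <- suppressMessages(read_expression(file.path(dir, "genes.tsv"),
                                           file.path(dir, "samples.tsv"),
                                           "gene"))
  expect_equal(back$values, ds$genes$values, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "annotations.tsv")))
  expect_true(any(startsWith(list.files(dir), "interactions_")))
})
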