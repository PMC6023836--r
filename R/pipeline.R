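#' Default per-resource score cutoffs for the bundled pseudo-resources
#'
#' Placeholder "creator-recommended" cutoffs for the synthetic resources of
#' [default_resources()]; real resources need their own configured values.
#' @return Named list of `list(threshold, direction)`.
#' @export
default_cutoffs <- function() {
  list(predictA = list(threshold = 70, direction = "higher"),
       predictB = list(threshold = 0.4, direction = "higher"),
       predictC = list(threshold = -12, direction = "lower"))
}

#' Assemble a pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one flat list. All
#' defaults mirror the analysis conventions of the package: expression
#' threshold 5 (log2), DE at adjusted p <= 1e-5 and |log2FC| >= 2,
#' anti-correlation at Kendall tau < -0.4 (developmental stages), dominance
#' fraction 0.5, regulator shortlist at >= 10, template similarity 0.6,
#' 6 gene clusters and 3 miRNA clusters.
#'
#' @param out_dir output directory.
#' @param seed integer seed controlling the synthetic data and clustering
#'   restarts.
#' @param simulate generate synthetic inputs (`TRUE`) or read them from
#'   `paths` (a named list: genes, mirnas, samples, annotations, and one
#'   `interactions_<resource>` entry per resource).
#' @param ... overrides for any default listed below.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir = tempfile("mirtempo_run_"), seed = 1L,
                            simulate = TRUE, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
    paths = NULL,
    expression_threshold = 5,
    p_threshold = 1e-5, lfc_threshold = 2,
    references = c("young", "E19.5"),
    tau_threshold = -0.4, correlation_mode = "dev",
    dominance_fraction = 0.5,
    regulator_min_count = 10,
    template_mirna = NULL, template_threshold = 0.6,
    n_gene_clusters = 6L, n_mirna_clusters = 3L,
    cutoffs = default_cutoffs(),
    synthetic = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg)))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

#' Parse a flat key/value pipeline configuration file
#'
#' Accepts lines of the form `key: value`; `#` starts a comment. Values are
#' coerced to numeric where possible, `true`/`false` to logical, and
#' comma-separated values to vectors.
#'
#' @param path file path.
#' @return A named list suitable for splicing into [pipeline_config()].
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    coerce <- function(v) {
      if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }
    vals <- lapply(parts, coerce)
    out[[key]] <- if (length(vals) == 1) vals[[1]] else unlist(vals)
  }
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full integrative pipeline
#'
#' Executes: simulate (or load) -> expression filter -> differential
#' expression against both references (genes and miRNAs) -> fuzzy c-means
#' clustering of DE features (full series, plus embryonic-only miRNA
#' re-clustering) -> interaction integration (score cutoffs, percentiles,
#' expression restriction) -> Kendall anti-correlation annotation and
#' cluster link matrices -> miRNA prioritization (DETG/DETGNC, regulator
#' counting, stringent filter, optional template match) -> per-cluster
#' category enrichment. All outputs are TSVs under `config$out_dir`; a
#' `manifest.jsonl` records row counts and md5 checksums so reruns can be
#' verified bit-identical.
#'
#' @param config a [pipeline_config()] object.
#' @return Invisibly, a list with the key in-memory results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- write_tsv(x, file.path(config$out_dir, name))
    outputs <<- c(outputs, p)
    x
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  dataset <- step("input", {
    if (isTRUE(config$simulate)) {
      scfg <- config$synthetic
      if (is.null(scfg)) scfg <- synthetic_config(seed = config$seed)
      generate_dataset(scfg)
    } else {
      load_dataset_paths(config$paths)
    }
  })
  annotations <- dataset$annotations

  # --- expression filter --------------------------------------------------
  filt <- step("filter", {
    fg <- filter_expressed(dataset$genes, config$expression_threshold)
    fm <- filter_expressed(dataset$mirnas, config$expression_threshold)
    list(genes = fg$matrix, mirnas = fm$matrix,
         dropped_genes = fg$dropped, dropped_mirnas = fm$dropped)
  })

  # --- differential expression -------------------------------------------
  de <- step("de", {
    refs <- intersect(config$references, filt$genes$stage_levels)
    res <- list()
    for (ref in refs) {
      res[[paste0("genes_", ref)]] <-
        de_vs_reference(filt$genes, ref, config$p_threshold,
                        config$lfc_threshold)
      res[[paste0("mirnas_", ref)]] <-
        de_vs_reference(filt$mirnas, ref, config$p_threshold,
                        config$lfc_threshold)
    }
    res
  })
  for (nm in names(de)) emit(de[[nm]], paste0("de_", nm, ".tsv"))
  primary_ref <- intersect(config$references, filt$genes$stage_levels)[1]
  de_genes <- de[[paste0("genes_", primary_ref)]]
  de_mirnas <- de[[paste0("mirnas_", primary_ref)]]
  de_gene_ids <- unique(de_genes$feature_id[de_genes$is_DE])
  de_mirna_ids <- unique(de_mirnas$feature_id[de_mirnas$is_DE])
  emit(summarize_de_counts(de_genes), "de_counts_genes.tsv")
  emit(summarize_de_counts(de_mirnas), "de_counts_mirnas.tsv")

  # --- clustering ---------------------------------------------------------
  cl <- step("cluster", {
    gene_prof <- stage_means(filt$genes)
    mir_prof <- stage_means(filt$mirnas)
    fit_for <- function(prof, ids, c, seed_off) {
      ids <- intersect(ids, rownames(prof))
      std <- standardize_profiles(prof[ids, , drop = FALSE])
      c_eff <- min(c, nrow(std$profiles))
      order_clusters(fuzzy_cmeans(std$profiles, c_eff,
                                  seed = config$seed + seed_off))
    }
    genes_model <- fit_for(gene_prof, de_gene_ids, config$n_gene_clusters, 11L)
    mirnas_model <- fit_for(mir_prof, de_mirna_ids, config$n_mirna_clusters, 12L)
    mir_dev <- stage_means(filt$mirnas, dev_only = TRUE)
    mirnas_dev_model <- fit_for(mir_dev, de_mirna_ids,
                                config$n_mirna_clusters, 13L)
    list(genes = genes_model, mirnas = mirnas_model,
         mirnas_dev = mirnas_dev_model,
         gene_prof = gene_prof, mir_prof = mir_prof)
  })
  emit(data.frame(feature_id = names(cl$genes$cluster),
                  cluster = unname(cl$genes$cluster)), "clusters_genes.tsv")
  emit(data.frame(feature_id = names(cl$mirnas$cluster),
                  cluster = unname(cl$mirnas$cluster)), "clusters_mirnas.tsv")

  # --- target integration -------------------------------------------------
  integrated <- step("integrate", {
    recs <- dataset$interactions
    by_res <- split(recs, recs$resource)
    filtered <- lapply(names(by_res), function(r) {
      x <- by_res[[r]]
      if (all(x$evidence == "experimental")) return(x)
      x <- filter_by_score(x, config$cutoffs)
      score_to_percentile(x, r, config$cutoffs[[r]]$direction)
    })
    merged <- do.call(merge_resources, filtered)
    expressed_g <- rownames(filt$genes$values)
    expressed_m <- rownames(filt$mirnas$values)
    merged$records <- restrict_to_expressed(merged$records, expressed_g,
                                            expressed_m)
    merged
  })
  emit(integrated$records, "interactions_integrated.tsv")

  # --- correlation network ------------------------------------------------
  net <- step("correlate", {
    correlated <- annotate_correlations(integrated$records, cl$mir_prof,
                                        cl$gene_prof, config$tau_threshold,
                                        config$correlation_mode)
    matrices <- build_link_matrices(correlated, cl$mirnas$cluster,
                                    cl$genes$cluster)
    links <- dominant_links(matrices, config$dominance_fraction)
    list(correlated = correlated, matrices = matrices, links = links)
  })
  emit(net$correlated, "correlations.tsv")
  emit(as.data.frame(net$matrices$M_all), "M_all.tsv")
  emit(as.data.frame(net$matrices$M_neg), "M_neg.tsv")
  emit(net$links, "dominant_links.tsv")

  # --- prioritization -----------------------------------------------------
  prio <- step("prioritize", {
    # the prioritization universe is the DEmiR set: only differentially
    # expressed miRNAs are candidates
    stats_tab <- detg_stats(net$correlated, de_gene_ids,
                            mirna_ids = de_mirna_ids)
    reg <- count_anticorr_regulators(net$correlated, annotations,
                                     config$regulator_min_count)
    stringent <- stringent_filter(net$correlated, max_abs_lfc(de_mirnas),
                                  max_abs_lfc(de_genes), annotations,
                                  config$lfc_threshold, config$tau_threshold,
                                  config$correlation_mode)
    tmpl <- NULL
    if (!is.null(config$template_mirna))
      tmpl <- template_match(config$template_mirna, cl$mir_prof,
                             config$template_threshold)
    list(stats = stats_tab, regulators = reg, stringent = stringent,
         template = tmpl)
  })
  emit(prio$stats, "prioritization.tsv")
  emit(prio$regulators, "regulator_counts.tsv")
  emit(prio$stringent, "stringent_candidates.tsv")
  if (!is.null(prio$template)) emit(prio$template, "template_matches.tsv")

  # --- enrichment ---------------------------------------------------------
  enr <- step("enrich", {
    universe <- rownames(filt$genes$values)
    rows <- lapply(seq_len(cl$genes$c), function(k) {
      members <- names(cl$genes$cluster)[cl$genes$cluster == k]
      if (!length(members)) return(NULL)
      res <- hypergeom_enrichment(members, annotations, universe)
      if (nrow(res)) cbind(cluster = k, res) else NULL
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(cluster = integer(0))
    out
  })
  emit(enr, "enrichment.tsv")

  # --- manifest -----------------------------------------------------------
  manifest <- data.frame(
    file = basename(outputs),
    rows = vapply(outputs, function(p) length(readLines(p)) - 1L, integer(1)),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.jsonl")
  con <- file(manifest_path, "w")
  writeLines(sprintf('{"file": "%s", "rows": %d, "md5": "%s"}',
                     manifest$file, manifest$rows, manifest$md5), con)
  writeLines(sprintf('{"seed": %d, "thresholds": "p=%g,lfc=%g,tau=%g,expr=%g"}',
                     config$seed, config$p_threshold, config$lfc_threshold,
                     config$tau_threshold, config$expression_threshold), con)
  close(con)

  invisible(list(dataset = dataset, filtered = filt, de = de, clusters = cl,
                 integrated = integrated, network = net,
                 prioritization = prio, enrichment = enr,
                 manifest = manifest))
}

# read a dataset from TSV paths (genes, mirnas, samples, annotations,
# interactions_<resource>...) as written by write_dataset()
load_dataset_paths <- function(paths) {
  if (is.null(paths)) stop("config$paths required when simulate = FALSE")
  need <- c("genes", "mirnas", "samples", "annotations")
  missing_p <- setdiff(need, names(paths))
  if (length(missing_p)) stop("missing input paths: ",
                              paste(missing_p, collapse = ", "))
  for (p in unlist(paths)) if (!file.exists(p)) stop("input path missing: ", p)
  genes <- read_expression(paths$genes, paths$samples, "gene")
  mirnas <- read_expression(paths$mirnas, paths$samples, "miRNA")
  ann <- utils::read.delim(paths$annotations, stringsAsFactors = FALSE)
  int_paths <- paths[startsWith(names(paths), "interactions_")]
  res <- default_resources()
  ints <- lapply(names(int_paths), function(nm) {
    r <- sub("^interactions_", "", nm)
    spec <- res[[r]]
    ev <- if (!is.null(spec)) spec$evidence else "predicted"
    dir <- if (!is.null(spec$direction)) spec$direction else "higher"
    read_interactions(int_paths[[nm]], r, ev, dir)
  })
  interactions <- do.call(rbind, ints)
  list(genes = genes, mirnas = mirnas, interactions = interactions,
       annotations = ann, truth = NULL)
}
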