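# End-to-end orchestration: simulate -> mine -> meta -> network -> enrich
# -> compare -> ml, from a single validated configuration, with stage
# caching keyed on the configuration hash and a machine-readable run report.

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]:
#' simulation sizes, the analysis thresholds (article-frequency filter > 50,
#' meta-analysis FDR <= 0.001, network filter |r| >= 0.5 and p <= 0.01,
#' proximity bound < 1 Mbp, locus bin 1 Mbp, 70/30 split, 95% CI), the
#' platform-group mapping, and the master seed. Any element may be
#' overridden before the run.
#'
#' @param out_dir output directory (created on demand).
#' @param seed master seed; stage seeds are derived from it.
#' @return named list (class `pipeline_config`).
#' @export
default_config <- function(out_dir = tempfile("genetriage_run_"), seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      n_genes = 150L, n_chromosomes = 10L,
      n_articles = 150L,
      n_frequent = 8L,       # genes planted above the article threshold
      n_infrequent = 12L,    # genes planted below it
      datasets = data.frame(
        dataset_id = c("DS_A1", "DS_A2", "DS_B1"),
        platform_id = c("PA", "PA", "PB"),
        n_case = c(12L, 10L, 12L), n_control = c(14L, 12L, 12L),
        stringsAsFactors = FALSE),
      de_fraction = 0.08, effect_size = 2.5, noise_sd = 1,
      corr_blocks = list(c(5, 0.9)),
      n_biomarkers = 3L, biomarker_effect = 3,
      n_terms = 40L, term_size_range = c(5L, 30L)),
    thresholds = list(
      min_articles = 50L, alpha = 0.001, r_min = 0.5, p_max = 0.01,
      max_dist = 1e6, bin_size = 1e6, split = 0.7, fdr_max = 0.05,
      top_k = 10L, n_trees = 200L, min_term_size = 5L),
    platform_groups = list(A = c("DS_A1", "DS_A2"), B = "DS_B1"),
    algorithms = c("decision_tree", "random_forest", "extra_trees")
  ), class = "pipeline_config")
}

validate_config <- function(config) {
  th <- config$thresholds
  probs <- c(alpha = th$alpha, r_min = th$r_min, p_max = th$p_max,
             split = th$split, fdr_max = th$fdr_max)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    stop_arg("invalid config: threshold(s) outside [0, 1]: %s",
             paste(bad, collapse = ", "))
  if (th$min_articles < 0 || th$max_dist <= 0 || th$bin_size <= 0)
    stop_arg("invalid config: min_articles >= 0 and positive distances required")
  sim_ids <- config$simulate$datasets$dataset_id
  grp_ids <- unlist(config$platform_groups, use.names = FALSE)
  if (!all(grp_ids %in% sim_ids))
    stop_arg("invalid config: platform_groups reference unknown datasets: %s",
             paste(setdiff(grp_ids, sim_ids), collapse = ", "))
  invisible(TRUE)
}

# stage caching: each stage directory carries a manifest with the config
# hash; outputs under a different hash are refused (or wiped with force).
stage_manifest_path <- function(out_dir, stage) {
  file.path(out_dir, stage, "manifest.json")
}

stage_cached <- function(out_dir, stage, hash) {
  mp <- stage_manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  identical(man$config_hash, hash) &&
    all(file.exists(file.path(out_dir, stage, unlist(man$files))))
}

write_stage <- function(out_dir, stage, hash, writer) {
  if (stage_cached(out_dir, stage, hash)) {   # resume from cached outputs
    man <- jsonlite::read_json(stage_manifest_path(out_dir, stage))
    return(invisible(unlist(man$files)))
  }
  dir <- file.path(out_dir, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- writer(dir)
  jsonlite::write_json(list(stage = stage, config_hash = hash,
                            files = as.list(files)),
                       stage_manifest_path(out_dir, stage),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> mine -> de-meta -> network -> enrich -> compare ->
#' ml in dependency order on synthetic inputs generated under the config's
#' seed, writing every stage's outputs (TSV/GMT/JSON) plus a `manifest.json`
#' carrying the configuration hash. Rerunning with the same configuration
#' reuses cached stage outputs and reproduces byte-identical files; an
#' output directory holding results from a *different* configuration is
#' refused unless `force = TRUE`.
#'
#' @param config a [default_config()]-style list.
#' @param force overwrite outputs from a different configuration?
#' @return run report (list, class `pipeline_report`): per-stage status
#'   plus headline counts; also written to `run_report.json`.
#' @export
run_pipeline <- function(config = default_config(), force = FALSE) {
  validate_config(config)
  hash <- object_hash(config[setdiff(names(config), "out_dir")])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "mine", "meta", "network", "enrich", "compare", "ml")
  for (st in stages) {   # refuse mixing outputs from different configs
    mp <- stage_manifest_path(out_dir, st)
    if (file.exists(mp)) {
      man <- jsonlite::read_json(mp)
      if (!identical(man$config_hash, hash) && !force)
        stop_arg("output dir %s holds stage '%s' from a different configuration; use force = TRUE",
                 out_dir, st)
    }
  }
  th <- config$thresholds
  sim <- config$simulate
  status <- list()

  ## ---- simulate -------------------------------------------------------
  catalog <- generate_catalog(sim$n_genes, sim$n_chromosomes, seed = config$seed)
  freq_syms <- catalog$genes$symbol[seq_len(sim$n_frequent)]
  rare_syms <- catalog$genes$symbol[sim$n_frequent + seq_len(sim$n_infrequent)]
  plan <- c(stats::setNames(
    th$min_articles + 1L + (seq_along(freq_syms) - 1L) * 3L, freq_syms),
    stats::setNames(rep(5L, length(rare_syms)), rare_syms))
  plan <- pmin(plan, sim$n_articles)
  corpus <- generate_corpus(catalog, sim$n_articles, plan, seed = config$seed + 1L)
  datasets <- generate_expression(
    catalog, sim$datasets, de_fraction = sim$de_fraction,
    effect_size = sim$effect_size, noise_sd = sim$noise_sd,
    corr_block_spec = sim$corr_blocks, n_biomarkers = sim$n_biomarkers,
    biomarker_effect = sim$biomarker_effect, seed = config$seed + 2L)
  annotations <- generate_annotations(
    catalog, sim$n_terms, sim$term_size_range,
    enriched_term_spec = list(term_id = "T_PLANTED",
                              term_name = "planted enriched term",
                              genes = freq_syms, size = max(sim$term_size_range)),
    seed = config$seed + 3L)
  status$simulate <- write_stage(out_dir, "simulate", hash, function(dir) {
    write_catalog(catalog, file.path(dir, "catalog.bed"))
    write_corpus(corpus, file.path(dir, "corpus.tsv"))
    for (ds in datasets) write_expression(ds, file.path(dir, paste0(ds$dataset_id, ".tsv")))
    write_gmt(annotations, file.path(dir, "annotations.gmt"))
    jsonlite::write_json(corpus$truth, file.path(dir, "truth_mentions.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    c("catalog.bed", "corpus.tsv", paste0(names(datasets), ".tsv"),
      "annotations.gmt", "truth_mentions.json")
  })

  ## ---- mine -----------------------------------------------------------
  index <- build_index(corpus, catalog)
  freq <- filter_frequent(index, th$min_articles)
  chrom_dist <- chromosome_distribution(freq, catalog)
  status$mine <- write_stage(out_dir, "mine", hash, function(dir) {
    write_tsv(as.data.frame(freq), file.path(dir, "frequency_table.tsv"))
    write_tsv(data.frame(chromosome = names(chrom_dist),
                         n_genes = unname(chrom_dist)),
              file.path(dir, "chromosome_distribution.tsv"))
    jsonlite::write_json(list(n_articles_scanned = index$n_articles_scanned,
                              min_articles = th$min_articles,
                              n_frequent = nrow(freq)),
                         file.path(dir, "mining_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    c("frequency_table.tsv", "chromosome_distribution.tsv", "mining_summary.json")
  })

  ## ---- meta -----------------------------------------------------------
  meta <- meta_analyze(datasets)
  degs <- select_degs(meta, th$alpha)
  status$meta <- write_stage(out_dir, "meta", hash, function(dir) {
    write_tsv(as.data.frame(meta), file.path(dir, "meta_table.tsv"))
    write_tsv(degs, file.path(dir, "deg_list.tsv"))
    c("meta_table.tsv", "deg_list.tsv")
  })

  ## ---- network (per platform group, pooled within group) --------------
  union_genes <- union(freq$symbol, degs$gene)
  networks <- lapply(names(config$platform_groups), function(grp) {
    dss <- datasets[config$platform_groups[[grp]]]
    gmats <- lapply(dss, function(ds) collapse_markers(ds$matrix, ds$marker_to_gene))
    gmat <- do.call(cbind, gmats)
    keep <- intersect(union_genes, rownames(gmat))
    if (length(keep) < 2) return(NULL)
    build_network(gmat[keep, , drop = FALSE], th$r_min, th$p_max, group_id = grp)
  })
  names(networks) <- names(config$platform_groups)
  networks <- Filter(Negate(is.null), networks)
  status$network <- write_stage(out_dir, "network", hash, function(dir) {
    files <- character()
    for (net in networks) {
      f <- paste0("edges_", net$group_id, ".tsv")
      write_tsv(net$edges, file.path(dir, f))
      h <- paste0("hubs_", net$group_id, ".tsv")
      write_tsv(hub_rank(net, th$top_k), file.path(dir, h))
      files <- c(files, f, h)
    }
    files
  })

  ## ---- enrich (mined list and DEG list) -------------------------------
  enr_mine <- enrich(freq$symbol, annotations, th$min_term_size)
  enr_deg <- if (nrow(degs)) enrich(degs$gene, annotations, th$min_term_size) else NULL
  status$enrich <- write_stage(out_dir, "enrich", hash, function(dir) {
    write_enrichment(enr_mine, file.path(dir, "enrichment_mined.tsv"))
    files <- "enrichment_mined.tsv"
    if (!is.null(enr_deg)) {
      write_enrichment(enr_deg, file.path(dir, "enrichment_deg.tsv"))
      files <- c(files, "enrichment_deg.tsv")
    }
    files
  })

  ## ---- compare --------------------------------------------------------
  report_cmp <- compare_gene_lists(freq$symbol, degs$gene, catalog,
                                   max_dist = th$max_dist,
                                   bin_size = th$bin_size,
                                   enrich_a = enr_mine, enrich_b = enr_deg,
                                   fdr_max = th$fdr_max)
  status$compare <- write_stage(out_dir, "compare", hash, function(dir) {
    write_tsv(report_cmp$proximity_pairs, file.path(dir, "proximity_pairs.tsv"))
    write_tsv(report_cmp$shared_loci, file.path(dir, "shared_loci.tsv"))
    jsonlite::write_json(list(shared_names = report_cmp$shared_names,
                              n_proximity_pairs = report_cmp$n_proximity_pairs,
                              n_proximity_genes = report_cmp$n_proximity_genes,
                              shared_terms = report_cmp$shared_terms),
                         file.path(dir, "comparison.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    c("proximity_pairs.tsv", "shared_loci.tsv", "comparison.json")
  })

  ## ---- ml -------------------------------------------------------------
  features <- assemble_features(datasets, union_genes, config$platform_groups)
  reports <- list()
  for (grp in names(features)) {
    split <- split_70_30(features[[grp]], seed = config$seed + 10L,
                         train_frac = th$split)
    for (alg in config$algorithms) {
      reports[[paste(grp, alg, sep = "_")]] <-
        train_and_score(split$train, split$test, alg,
                        n_trees = th$n_trees, seed = config$seed + 20L)
    }
  }
  tally <- tally_recurrence(reports, th$top_k)
  status$ml <- write_stage(out_dir, "ml", hash, function(dir) {
    files <- character()
    for (nm in names(reports)) {
      r <- reports[[nm]]
      f <- paste0("model_", nm, ".json")
      jsonlite::write_json(
        list(algorithm = r$algorithm, group = r$group_id,
             accuracy = r$accuracy, ci_low = r$ci_low, ci_high = r$ci_high,
             n_test = r$n_test,
             top_importances = utils::head(r$importances, th$top_k)),
        file.path(dir, f), auto_unbox = TRUE, pretty = TRUE, digits = NA)
      files <- c(files, f)
    }
    write_tsv(tally$markers, file.path(dir, "recurrent_markers.tsv"))
    write_tsv(tally$genes, file.path(dir, "recurrent_genes.tsv"))
    c(files, "recurrent_markers.tsv", "recurrent_genes.tsv")
  })

  report <- list(config_hash = hash,
                 stages = stats::setNames(
                   lapply(names(status), function(s)
                     list(status = "succeeded", files = unlist(status[[s]]))),
                   names(status)),
                 n_frequent_genes = nrow(freq),
                 n_degs = nrow(degs),
                 n_network_edges = sum(vapply(networks, function(n) nrow(n$edges),
                                              numeric(1))),
                 shared_names = report_cmp$shared_names,
                 accuracies = stats::setNames(
                   lapply(reports, function(r)
                     list(accuracy = r$accuracy, ci_low = r$ci_low,
                          ci_high = r$ci_high)), names(reports)))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d stages succeeded; %d frequent genes, %d DEGs, %d network edges\n",
              length(x$stages), x$n_frequent_genes, x$n_degs, x$n_network_edges))
  invisible(x)
}
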