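# End-to-end orchestration: simulate (or load) -> quantify -> per-pair DE ->
# target prediction -> negative regulatory network -> enrichment, with a
# validated config, structured stderr logging and a reproducibility manifest.
# All intermediate artifacts are plain TSV/FASTA/JSON.

pipeline_config_template <- function() {
  list(
    mode = "simulate",            # "simulate" or "files"
    input_dir = NULL,             # cohort directory when mode = "files"
    sim = as.list(unclass(simulation_config())),
    de = list(
      dispersion = NULL,  # NULL: generative dispersion when simulating, else 0.1
      fc_threshold = 1.5, fdr_threshold = 0.05,
      cpm_threshold = 1, cpm_min_samples = 1
    ),
    targets = list(
      w_au = 0.1, w_pos = 0.1, align_min = NULL, align_min_frac = 0.9,
      context_threshold = 0, scan_scope = "de"   # "de" or "all"
    ),
    network = list(min_pairs = 2, pattern = "miR_up_gene_down"),
    enrichment = list(method = "hypergeometric", top_k = 15),
    rng_seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML or JSON file path, or a nested list, and returns a
#' fully-defaulted validated configuration. Unknown keys at any level are
#' rejected; threshold domains are checked. The single `rng_seed` governs
#' every stochastic stage through fixed per-stage offsets.
#'
#' @param config A path to a YAML/JSON file, a list of overrides, or `NULL`
#'   for pure defaults.
#' @return A validated `mir_pipeline_config` list.
#' @export
#' @examples
#' cfg <- validate_config(list(rng_seed = 42, network = list(min_pairs = 3)))
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) cfg_error(sprintf("config file '%s' does not exist", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- config %||% list()
  if (inherits(config, "mir_pipeline_config")) config <- unclass(config)
  if (!is.list(config)) cfg_error("config must be a list or a YAML/JSON file path")
  tpl <- pipeline_config_template()
  merge_checked <- function(base, override, path) {
    unknown <- setdiff(names(override), names(base))
    if (length(unknown) > 0) {
      cfg_error(sprintf("unknown config key%s: %s",
                        if (length(unknown) > 1) "s" else "",
                        paste0(path, unknown, collapse = ", ")))
    }
    for (k in names(override)) {
      if (is.list(base[[k]]) && is.list(override[[k]]) && !is.null(names(base[[k]]))) {
        base[[k]] <- merge_checked(base[[k]], override[[k]], paste0(path, k, "."))
      } else {
        base[k] <- list(override[[k]])  # keeps explicit NULLs in place
      }
    }
    base
  }
  cfg <- merge_checked(tpl, config, "")
  if (!cfg$mode %in% c("simulate", "files")) cfg_error("mode must be 'simulate' or 'files'")
  if (cfg$mode == "files") {
    if (is.null(cfg$input_dir)) cfg_error("input_dir is required when mode = 'files'")
    if (!dir.exists(cfg$input_dir)) {
      cfg_error(sprintf("input_dir '%s' does not exist", cfg$input_dir))
    }
  }
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!in01(cfg$de$fdr_threshold)) cfg_error("de.fdr_threshold must lie in (0, 1]")
  if (!is.numeric(cfg$de$fc_threshold) || cfg$de$fc_threshold < 1) {
    cfg_error("de.fc_threshold must be >= 1")
  }
  if (!is.null(cfg$de$dispersion) && cfg$de$dispersion < 0) {
    cfg_error("de.dispersion must be >= 0")
  }
  if (cfg$de$cpm_threshold < 0) cfg_error("de.cpm_threshold must be >= 0")
  if (cfg$targets$w_au < 0 || cfg$targets$w_pos < 0) {
    cfg_error("targets.w_au and targets.w_pos must be >= 0")
  }
  if (!is.null(cfg$targets$align_min) && cfg$targets$align_min < 0) {
    cfg_error("targets.align_min must be >= 0")
  }
  if (cfg$targets$align_min_frac <= 0 || cfg$targets$align_min_frac > 1.5) {
    cfg_error("targets.align_min_frac must lie in (0, 1.5]")
  }
  if (!cfg$targets$scan_scope %in% c("de", "all")) {
    cfg_error("targets.scan_scope must be 'de' or 'all'")
  }
  if (cfg$network$min_pairs < 1) cfg_error("network.min_pairs must be >= 1")
  if (!cfg$network$pattern %in% c("miR_up_gene_down", "miR_down_gene_up")) {
    cfg_error("network.pattern must be a valid edge pattern")
  }
  if (!cfg$enrichment$method %in% c("hypergeometric", "wallenius")) {
    cfg_error("enrichment.method must be 'hypergeometric' or 'wallenius'")
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$sim$rng_seed <- cfg$rng_seed
  structure(cfg, class = "mir_pipeline_config")
}

log_stage <- function(stage, msg) {
  message(sprintf("[mircoop] %s | %s | %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> quantify -> per-pair DE -> target prediction ->
#' network -> enrichment in order, writing each stage's plain-text artifacts
#' plus a JSON manifest into `outdir`. Identical config and seed produce
#' byte-identical outputs. Structured stage logs go to standard error.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the `manifest`, the `mir_cohort` used, DE
#'   tables, target calls, the filtered `mir_network` and the TF subnetwork.
#' @export
run_pipeline <- function(config = NULL, outdir) {
  cfg <- validate_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  t0 <- Sys.time()

  # stage 1: cohort
  cohort <- if (cfg$mode == "simulate") {
    log_stage("simulate", sprintf("generating synthetic cohort (seed %d)", cfg$rng_seed))
    simulate_cohort(do.call(simulation_config, cfg$sim))
  } else {
    log_stage("load", sprintf("reading cohort from %s", cfg$input_dir))
    read_cohort(cfg$input_dir)
  }
  if (cfg$mode == "simulate") write_cohort(cohort, p("cohort"))

  # stage 2: quantification
  log_stage("quantify", "RPKM / TPM / CPM")
  write_norm_tsv(compute_rpkm(cohort$mrna$counts, cohort$mrna$samples), p("mrna_rpkm.tsv"))
  write_norm_tsv(compute_tpm_mirna(cohort$mirna$counts, cohort$mirna$samples), p("mirna_tpm.tsv"))
  write_norm_tsv(compute_cpm(cohort$mrna$counts), p("mrna_cpm.tsv"))

  # stage 3: per-pair DE; NULL dispersion resolves to the generative value
  # for simulated cohorts (known truth) and to 0.1 otherwise
  de_args <- cfg$de
  if (is.null(de_args$dispersion)) {
    de_args$dispersion <- if (cfg$mode == "simulate") cohort$config$nb_dispersion else 0.1
  }
  run1 <- function(counts, samples) {
    run_de(counts, samples,
           dispersion = de_args$dispersion, fc_threshold = de_args$fc_threshold,
           fdr_threshold = de_args$fdr_threshold, cpm_threshold = de_args$cpm_threshold,
           cpm_min_samples = de_args$cpm_min_samples)
  }
  log_stage("de", "mRNA per-pair exact tests")
  de_mrna <- run1(cohort$mrna$counts, cohort$mrna$samples)
  log_stage("de", "miRNA per-pair exact tests")
  de_mirna <- run1(cohort$mirna$counts, cohort$mirna$samples)
  readr::write_tsv(de_mrna, p("de_mrna.tsv"))
  readr::write_tsv(de_mirna, p("de_mirna.tsv"))
  readr::write_tsv(de_venn_counts(de_mrna), p("venn_mrna.tsv"))
  readr::write_tsv(de_venn_counts(de_mirna), p("venn_mirna.tsv"))

  # stage 4: target prediction
  de_m_ids <- unique(de_mirna$feature_id[de_mirna$direction != "ns"])
  de_g_ids <- unique(de_mrna$feature_id[de_mrna$direction != "ns"])
  scan_genes <- if (cfg$targets$scan_scope == "de") {
    cohort$genes[cohort$genes$gene_id %in% de_g_ids, ]
  } else cohort$genes
  scan_mirnas <- if (cfg$targets$scan_scope == "de") {
    cohort$mirnas[cohort$mirnas$mirna_id %in% de_m_ids, ]
  } else cohort$mirnas
  log_stage("targets", sprintf("scanning %d miRNAs x %d UTRs",
                               nrow(scan_mirnas), nrow(scan_genes)))
  sites <- find_target_sites(scan_genes, scan_mirnas,
                             w_au = cfg$targets$w_au, w_pos = cfg$targets$w_pos)
  calls <- call_targets_all(sites, scan_mirnas,
                            align_min = cfg$targets$align_min,
                            align_min_frac = cfg$targets$align_min_frac,
                            context_threshold = cfg$targets$context_threshold)
  write_scores_tsv(sites, p("target_sites.tsv"))
  write_scores_tsv(calls, p("target_calls.tsv"))

  # stage 5: network
  log_stage("network", "matching sign-opposite DE with target calls")
  edges_all <- match_negative_pairs(de_mirna, de_mrna, calls)
  edges <- apply_recurrence_filter(edges_all, cfg$network$min_pairs)
  if (nrow(edges) == 0) {
    log_stage("network", "warning: no edges survive the recurrence filter")
  }
  tf_ids <- cohort$genes$gene_id[cohort$genes$is_tf]
  network <- as_mir_network(edges, tf_ids = tf_ids, min_pairs = cfg$network$min_pairs)
  tf_net <- build_tf_subnetwork(network, tf_ids, pattern = cfg$network$pattern)
  readr::write_tsv(tidy_edges(edges_all), p("edges_unfiltered.tsv"))
  export_edge_list(network, p("edges.tsv"), "tsv")
  export_edge_list(tf_net, p("tf_network.sif"), "sif")
  write_node_attributes(network, p("node_attributes.tsv"))
  readr::write_tsv(hub_statistics(tf_net), p("tf_hub_statistics.tsv"))

  # stage 6: enrichment of coordinately down-regulated genes
  log_stage("enrich", "GO-style term enrichment")
  rec <- summarize_recurrence(de_mrna)
  study <- rec$feature_id[rec$coordinated &
                            map_int(rec$pairs_down, length) > 0]
  universe <- unique(de_mrna$feature_id)
  terms <- go_term_map(cohort$genes)
  enr <- if (length(study) > 0) {
    hypergeom_enrich(study, universe, terms)
  } else {
    hypergeom_enrich(universe[1], universe, terms)[0, ]
  }
  readr::write_tsv(enr, p("enrichment_down.tsv"))

  manifest <- list(
    artifact = "mircoop",
    version = as.character(packageVersion("mircoop")),
    rng_seed = cfg$rng_seed,
    config = unclass(cfg),
    counts = list(
      mrna_features_tested = length(unique(de_mrna$feature_id)),
      mirna_features_tested = length(unique(de_mirna$feature_id)),
      de_calls_mrna_per_pair = de_mrna |> filter(.data$direction != "ns") |>
        count(.data$pair_id) |> tibble::deframe() |> as.list(),
      de_calls_mirna_per_pair = de_mirna |> filter(.data$direction != "ns") |>
        count(.data$pair_id) |> tibble::deframe() |> as.list(),
      target_calls_passing = sum(calls$passes),
      edges_prefilter = nrow(edges_all),
      edges_postfilter = nrow(edges),
      tf_subnetwork_mirnas = sum(tf_net$nodes$role == "miRNA"),
      tf_subnetwork_tfs = sum(tf_net$nodes$role == "gene"),
      tf_subnetwork_edges = nrow(tf_net$edges),
      enriched_terms_fdr05 = sum(enr$fdr < 0.05)
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", sprintf("completed in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(
    manifest = manifest, cohort = cohort, de_mrna = de_mrna, de_mirna = de_mirna,
    sites = sites, calls = calls, edges_unfiltered = edges_all,
    network = network, tf_network = tf_net, enrichment = enr
  ))
}
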