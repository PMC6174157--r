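#' Configuration for the synthetic paired-cohort generator
#'
#' Builds and validates the parameter set for the synthetic tumor/normal
#' cohort. Defaults describe the study design the generator emulates: four
#' tumor/normal pairs, a few thousand genes of which a subset are
#' transcription factors (TFs), a few hundred miRNAs of which 40 are planted
#' as co-upregulated in every tumor, and one hub TF carrying a target site
#' for 25 distinct planted miRNAs (cooperative suppression).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_tfs Number of genes flagged as transcription factors (default 150).
#' @param n_mirnas Number of miRNAs (default 300).
#' @param n_pairs Number of tumor/normal pairs (default 4).
#' @param utr_length_range Integer interval of 3'UTR lengths in nt
#'   (default `c(200, 800)`).
#' @param nb_dispersion Negative-binomial dispersion phi of the counts
#'   (default 0.05); 0 gives Poisson counts. Modeled as a per-(feature,
#'   patient) gamma biological effect shared between the tumor and normal
#'   sample of a pair, with Poisson sampling noise on top, so each count is
#'   marginally NB(mean, phi) while within-pair ratios are sampling-limited
#'   (the rationale of a paired design).
#' @param baseline_log_mean `c(meanlog, sdlog)` of the log-normal relative
#'   expression levels (default `c(log(500), 0.8)`; only the shape matters,
#'   levels are rescaled to the library size).
#' @param planted_up_mirnas Number of miRNAs planted as upregulated in every
#'   tumor (default 40).
#' @param planted_down_mirnas Number of miRNAs planted as downregulated in
#'   every tumor (default 4); they carry no target sites.
#' @param planted_mirna_fc Tumor/normal fold change of planted up-miRNAs
#'   (default 4; must exceed 1.5). Planted down-miRNAs use its reciprocal.
#' @param hub_site_mirnas Number of distinct planted up-miRNAs with a site on
#'   the hub TF (default 25).
#' @param target_suppression_fc Multiplicative tumor fold change applied to a
#'   target gene per targeting miRNA (default 0.55; must be below 1/1.5).
#' @param suppression_floor Lower bound of the compounded suppression fold
#'   change (default 0.1).
#' @param n_target_genes Size of the shared target-gene pool of the planted
#'   up-miRNAs, hub included (default 60); 70% of the pool are TFs.
#' @param mirnas_per_target Integer range of planted miRNAs targeting each
#'   non-hub pool gene (default `c(8, 15)`).
#' @param background_de_frac Fraction of features given a pair-specific
#'   background fold change, independently in each pair (default 0.1).
#' @param background_lfc_sd Standard deviation of the background log fold
#'   changes (natural log; default `log(1.5)`, so background perturbations
#'   straddle the 1.5-fold calling threshold).
#' @param library_size_range Integer interval of per-sample library sizes in
#'   reads (default `c(1e6, 2e6)`, a desk-scaled sequencing depth).
#' @param min_rel_frac Floor on relative expression, as a fraction of the
#'   median level (default 0.4), so every feature is comfortably quantifiable.
#' @param n_go_terms Number of random GO-style terms to annotate genes with
#'   (default 25), in addition to one transcription-regulation term that
#'   contains exactly the TFs.
#' @param rng_seed Integer seed driving all generator stages (default 1).
#'
#' @return A validated `mir_sim_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 100, n_mirnas = 20, rng_seed = 7)
simulation_config <- function(n_genes = 2000,
                              n_tfs = 150,
                              n_mirnas = 300,
                              n_pairs = 4,
                              utr_length_range = c(200L, 800L),
                              nb_dispersion = 0.05,
                              baseline_log_mean = c(log(500), 0.8),
                              planted_up_mirnas = 40,
                              planted_down_mirnas = 4,
                              planted_mirna_fc = 4,
                              hub_site_mirnas = 25,
                              target_suppression_fc = 0.55,
                              suppression_floor = 0.1,
                              n_target_genes = 60,
                              mirnas_per_target = c(8L, 15L),
                              background_de_frac = 0.1,
                              background_lfc_sd = log(1.5),
                              library_size_range = c(1e6, 2e6),
                              min_rel_frac = 0.4,
                              n_go_terms = 25,
                              rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    n_mirnas = as.integer(n_mirnas), n_pairs = as.integer(n_pairs),
    utr_length_range = as.integer(utr_length_range),
    nb_dispersion = nb_dispersion, baseline_log_mean = baseline_log_mean,
    planted_up_mirnas = as.integer(planted_up_mirnas),
    planted_down_mirnas = as.integer(planted_down_mirnas),
    planted_mirna_fc = planted_mirna_fc,
    hub_site_mirnas = as.integer(hub_site_mirnas),
    target_suppression_fc = target_suppression_fc,
    suppression_floor = suppression_floor,
    n_target_genes = as.integer(n_target_genes),
    mirnas_per_target = as.integer(mirnas_per_target),
    background_de_frac = background_de_frac,
    background_lfc_sd = background_lfc_sd,
    library_size_range = as.numeric(library_size_range),
    min_rel_frac = min_rel_frac,
    n_go_terms = as.integer(n_go_terms),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "mir_sim_config"
  validate_sim_config(cfg)
}

#' @rdname simulation_config
#' @param config An object to validate as a `mir_sim_config`.
#' @export
validate_sim_config <- function(config) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) cfg_error(sprintf("invalid config field '%s': %s", field, why))
  }
  chk(length(config$n_genes) == 1 && config$n_genes >= 1, "n_genes", "must be a positive integer")
  chk(config$n_tfs >= 0 && config$n_tfs <= config$n_genes, "n_tfs", "must satisfy 0 <= n_tfs <= n_genes")
  chk(config$n_mirnas >= 1, "n_mirnas", "must be a positive integer")
  chk(config$n_pairs >= 2, "n_pairs", "must be >= 2")
  chk(length(config$utr_length_range) == 2 &&
        config$utr_length_range[1] >= 10 &&
        config$utr_length_range[2] >= config$utr_length_range[1],
      "utr_length_range", "must be a non-empty interval with lower bound >= 10 nt")
  chk(config$nb_dispersion >= 0, "nb_dispersion", "must be >= 0")
  chk(length(config$baseline_log_mean) == 2 && config$baseline_log_mean[2] >= 0,
      "baseline_log_mean", "must be c(meanlog, sdlog >= 0)")
  chk(config$planted_up_mirnas >= 0 && config$planted_up_mirnas <= config$n_mirnas,
      "planted_up_mirnas", "must be between 0 and n_mirnas")
  chk(config$planted_down_mirnas >= 0 &&
        config$planted_down_mirnas + config$planted_up_mirnas <= config$n_mirnas,
      "planted_down_mirnas", "up + down planted miRNAs must not exceed n_mirnas")
  chk(config$planted_mirna_fc > 1.5, "planted_mirna_fc", "must be > 1.5")
  chk(config$hub_site_mirnas >= 0 && config$hub_site_mirnas <= config$planted_up_mirnas,
      "hub_site_mirnas", "must not exceed planted_up_mirnas")
  chk(config$target_suppression_fc > 0 && config$target_suppression_fc < 1 / 1.5,
      "target_suppression_fc", "must lie in (0, 1/1.5)")
  chk(config$suppression_floor > 0 && config$suppression_floor <= 1,
      "suppression_floor", "must lie in (0, 1]")
  chk(config$n_target_genes >= 1 && config$n_target_genes <= config$n_genes,
      "n_target_genes", "must be between 1 and n_genes")
  chk(length(config$mirnas_per_target) == 2 &&
        config$mirnas_per_target[1] >= 0 &&
        config$mirnas_per_target[2] >= config$mirnas_per_target[1],
      "mirnas_per_target", "must be a non-empty integer interval")
  chk(config$background_de_frac >= 0 && config$background_de_frac <= 1,
      "background_de_frac", "must lie in [0, 1]")
  chk(config$background_lfc_sd >= 0, "background_lfc_sd", "must be >= 0")
  chk(length(config$library_size_range) == 2 &&
        config$library_size_range[1] > 0 &&
        config$library_size_range[2] >= config$library_size_range[1],
      "library_size_range", "must be a non-empty positive interval")
  chk(config$min_rel_frac >= 0 && config$min_rel_frac < 1, "min_rel_frac", "must lie in [0, 1)")
  chk(config$rng_seed == round(config$rng_seed), "rng_seed", "must be an integer")
  config
}

#' Generate a synthetic transcriptome
#'
#' Draws `n_genes` gene records: a random 3'UTR over \{A,C,G,U\}, a summed
#' exonic length (used by RPKM), a TF flag for `n_tfs` randomly chosen genes,
#' and GO-style term annotations. One term
#' (`GO:0006355`, regulation of transcription) contains exactly the TFs.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `gene_id`, `utr_seq`, `exonic_length`,
#'   `is_tf`, `go_terms` (list column of term ids).
#' @export
generate_transcriptome <- function(config) {
  config <- validate_sim_config(config)
  with_seed(stage_seed(config$rng_seed, "transcriptome"), {
    n <- config$n_genes
    ids <- sprintf("gene%05d", seq_len(n))
    lens <- sample(config$utr_length_range[1]:config$utr_length_range[2], n, replace = TRUE)
    utrs <- random_rna(lens)
    exonic <- sample(500:10000, n, replace = TRUE)
    is_tf <- rep(FALSE, n)
    if (config$n_tfs > 0) is_tf[sample.int(n, config$n_tfs)] <- TRUE
    terms <- sprintf("GO:SYN%03d", seq_len(config$n_go_terms))
    go <- lapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      sort(sample(terms, min(k, length(terms))))
    })
    go <- lapply(seq_len(n), function(i) {
      if (is_tf[i]) sort(unique(c(go[[i]], "GO:0006355"))) else go[[i]]
    })
    tibble(
      gene_id = ids, utr_seq = utrs, exonic_length = exonic,
      is_tf = is_tf, go_terms = go
    )
  })
}

#' Long-format GO term map of a synthetic transcriptome
#'
#' @param genes A gene tibble from [generate_transcriptome()].
#' @return A tibble with columns `term_id`, `term_name`, `gene_id`.
#' @export
go_term_map <- function(genes) {
  out <- genes |>
    select("gene_id", "go_terms") |>
    unnest("go_terms") |>
    rename(term_id = "go_terms")
  out |>
    mutate(term_name = ifelse(
      .data$term_id == "GO:0006355",
      "regulation of transcription, DNA-templated",
      sub("GO:SYN0*", "synthetic process ", .data$term_id)
    )) |>
    select("term_id", "term_name", "gene_id") |>
    arrange(.data$term_id, .data$gene_id)
}

#' Generate a synthetic mirnome
#'
#' Draws `n_mirnas` mature miRNA records of length 19-23 nt over \{A,C,G,U\}
#' and marks the planted up- and down-regulated subsets. Seed heptamers
#' (positions 2-8) are forced pairwise distinct among the planted up-miRNAs
#' so planted target sites are unambiguous.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `mirna_id`, `mature_seq`, `seed`,
#'   `planted_up`, `planted_down`.
#' @export
generate_mirnome <- function(config) {
  config <- validate_sim_config(config)
  if (config$planted_up_mirnas > 4^7) {
    gen_error("planted_up_mirnas exceeds the number of distinct seed heptamers (4^7)")
  }
  with_seed(stage_seed(config$rng_seed, "mirnome"), {
    n <- config$n_mirnas
    ids <- sprintf("miR-s%04d", seq_len(n))
    seqs <- random_rna(sample(19:23, n, replace = TRUE))
    planted_up <- rep(FALSE, n)
    planted_down <- rep(FALSE, n)
    if (config$planted_up_mirnas > 0) {
      planted_up[sample.int(n, config$planted_up_mirnas)] <- TRUE
    }
    rest <- which(!planted_up)
    if (config$planted_down_mirnas > 0) {
      planted_down[sample(rest, config$planted_down_mirnas)] <- TRUE
    }
    # enforce distinct seeds among the planted up-miRNAs
    up_idx <- which(planted_up)
    for (iter in seq_len(1000)) {
      seeds <- str_sub(seqs[up_idx], 2, 8)
      dup <- duplicated(seeds)
      if (!any(dup)) break
      redo <- up_idx[dup]
      seqs[redo] <- random_rna(sample(19:23, length(redo), replace = TRUE))
      if (iter == 1000) gen_error("could not draw pairwise distinct seeds for planted up-miRNAs")
    }
    tibble(
      mirna_id = ids, mature_seq = seqs, seed = str_sub(seqs, 2, 8),
      planted_up = planted_up, planted_down = planted_down
    )
  })
}

# Non-overlapping 1-based start positions for k sites of width 8 with at
# least one spacer base between consecutive sites, inside a UTR of length L.
plant_positions <- function(L, k) {
  if (k == 0) return(integer(0))
  span <- L - 7 - 9 * (k - 1)
  if (span < k) gen_error(sprintf("UTR of length %d too short to host %d sites", L, k))
  q <- sort(sample.int(span, k))
  q + 9 * (seq_len(k) - 1)
}

#' Plant cooperative miRNA target sites into synthetic UTRs
#'
#' Writes canonical 8mer sites (reverse complement of miRNA positions 2-8
#' followed by an A opposite position 1) into the 3'UTRs of a shared pool of
#' target genes. The hub TF receives one site for each of `hub_site_mirnas`
#' distinct planted up-miRNAs; every other pool gene is targeted by a number
#' of planted miRNAs drawn from `mirnas_per_target` (capped by what its UTR
#' can host without overlaps). Per-pair expression effects (planted fold
#' changes plus pair-specific background fold changes) are drawn here so that
#' count simulation is a pure read-out of the recorded truth.
#'
#' @param genes Gene tibble from [generate_transcriptome()].
#' @param mirnas miRNA tibble from [generate_mirnome()].
#' @param config The same [simulation_config()] used to generate them.
#' @return A list with `genes` (UTRs now containing the planted sites) and
#'   `truth`, a `mir_truth` list holding `up_mirna_ids`, `down_mirna_ids`,
#'   `target_map` (tibble `mirna_id`, `gene_id`, `utr_start` 0-based),
#'   `hub_gene_id` and `per_pair_effects` (tibble `pair_id`, `feature_id`,
#'   `feature_type`, `fc`).
#' @export
plant_target_sites <- function(genes, mirnas, config) {
  config <- validate_sim_config(config)
  up_ids <- mirnas$mirna_id[mirnas$planted_up]
  if (config$hub_site_mirnas > length(up_ids)) {
    gen_error("hub_site_mirnas exceeds the number of planted up-miRNAs")
  }
  with_seed(stage_seed(config$rng_seed, "plant"), {
    utr_len <- str_length(genes$utr_seq)
    target_map <- tibble(mirna_id = character(), gene_id = character(), utr_start = integer())
    hub_gene_id <- NA_character_
    if (length(up_ids) > 0 && config$n_target_genes > 0) {
      # hub: a TF whose UTR can host hub_site_mirnas non-overlapping sites
      need_hub <- 10 * config$hub_site_mirnas - 2
      hub_pool <- which(genes$is_tf & utr_len >= need_hub)
      if (config$hub_site_mirnas > 0 && length(hub_pool) == 0) {
        gen_error("no TF UTR long enough to host the hub sites")
      }
      hub_idx <- if (config$hub_site_mirnas > 0) sample(hub_pool, 1) else sample(which(genes$is_tf), 1)
      hub_gene_id <- genes$gene_id[hub_idx]
      # remaining pool: mostly TFs, mirroring a many-miRNA x many-TF network
      n_rest <- config$n_target_genes - 1
      n_tf_pool <- min(round(0.7 * n_rest), sum(genes$is_tf) - 1)
      tf_cand <- setdiff(which(genes$is_tf), hub_idx)
      other_cand <- which(!genes$is_tf)
      pool_idx <- c(
        if (n_tf_pool > 0) sample(tf_cand, n_tf_pool),
        if (n_rest - n_tf_pool > 0) sample(other_cand, min(n_rest - n_tf_pool, length(other_cand)))
      )
      lo <- config$mirnas_per_target[1]
      hi <- config$mirnas_per_target[2]
      utr <- genes$utr_seq
      entries <- list()
      for (gi in c(hub_idx, pool_idx)) {
        L <- utr_len[gi]
        k_cap <- max(0L, (L + 2L) %/% 10L)
        k <- if (gi == hub_idx) config$hub_site_mirnas else min(sample(lo:hi, 1), k_cap, length(up_ids))
        if (k == 0) next
        if (gi == hub_idx && k_cap < k) {
          gen_error(sprintf("hub UTR of length %d too short to host %d sites", L, k))
        }
        who <- sample(up_ids, k)
        pos <- plant_positions(L, k)          # 1-based starts of the 8mer site
        site_mirnas <- mirnas[match(who, mirnas$mirna_id), ]
        site8 <- paste0(rna_revcomp(site_mirnas$seed), "A")
        s <- utr[gi]
        for (j in seq_len(k)) {
          str_sub(s, pos[j], pos[j] + 7) <- site8[j]
        }
        utr[gi] <- s
        entries[[length(entries) + 1]] <- tibble(
          mirna_id = who, gene_id = genes$gene_id[gi], utr_start = pos - 1L
        )
      }
      genes$utr_seq <- utr
      if (length(entries) > 0) target_map <- bind_rows(entries)
    }
    # per-pair fold-change effects
    pair_ids <- sprintf("P%d", seq_len(config$n_pairs))
    tgt_counts <- target_map |> count(.data$gene_id, name = "k")
    gene_fc <- pmax(config$target_suppression_fc^tgt_counts$k, config$suppression_floor)
    effects <- list()
    for (p in pair_ids) {
      eff <- list()
      if (length(up_ids) > 0) {
        eff[[length(eff) + 1]] <- tibble(
          pair_id = p, feature_id = up_ids, feature_type = "mirna",
          fc = config$planted_mirna_fc
        )
      }
      down_ids <- mirnas$mirna_id[mirnas$planted_down]
      if (length(down_ids) > 0) {
        eff[[length(eff) + 1]] <- tibble(
          pair_id = p, feature_id = down_ids, feature_type = "mirna",
          fc = 1 / config$planted_mirna_fc
        )
      }
      if (nrow(tgt_counts) > 0) {
        eff[[length(eff) + 1]] <- tibble(
          pair_id = p, feature_id = tgt_counts$gene_id, feature_type = "gene",
          fc = gene_fc
        )
      }
      # pair-specific background effects on the remaining features
      bg_genes <- setdiff(genes$gene_id, tgt_counts$gene_id)
      n_bg <- round(config$background_de_frac * config$n_genes)
      if (n_bg > 0 && length(bg_genes) > 0) {
        pick <- sample(bg_genes, min(n_bg, length(bg_genes)))
        eff[[length(eff) + 1]] <- tibble(
          pair_id = p, feature_id = pick, feature_type = "gene",
          fc = exp(rnorm(length(pick), 0, config$background_lfc_sd))
        )
      }
      bg_mirnas <- mirnas$mirna_id[!mirnas$planted_up & !mirnas$planted_down]
      n_bgm <- round(config$background_de_frac * config$n_mirnas)
      if (n_bgm > 0 && length(bg_mirnas) > 0) {
        pick <- sample(bg_mirnas, min(n_bgm, length(bg_mirnas)))
        eff[[length(eff) + 1]] <- tibble(
          pair_id = p, feature_id = pick, feature_type = "mirna",
          fc = exp(rnorm(length(pick), 0, config$background_lfc_sd))
        )
      }
      effects[[p]] <- bind_rows(eff)
    }
    truth <- structure(list(
      up_mirna_ids = up_ids,
      down_mirna_ids = mirnas$mirna_id[mirnas$planted_down],
      target_map = target_map,
      hub_gene_id = hub_gene_id,
      per_pair_effects = bind_rows(
        tibble(pair_id = character(0), feature_id = character(0),
               feature_type = character(0), fc = numeric(0)),
        bind_rows(unname(effects))
      )
    ), class = "mir_truth")
    list(genes = genes, truth = truth)
  })
}

#' Simulate negative-binomial count matrices for a planted cohort
#'
#' Draws one tumor and one normal column per pair for both the mRNA and the
#' miRNA feature sets. Expected counts are library-size-scaled log-normal
#' baselines multiplied by the fold changes recorded in `truth`. Biological
#' dispersion is a per-(feature, patient) gamma effect shared between the
#' tumor and normal sample of a pair, with Poisson sampling noise on top, so
#' each count is marginally `NB(mean, nb_dispersion)` (Poisson when 0) while
#' within-pair fold changes are sampling-limited. Effects are applied
#' without renormalizing column totals, so planted fold changes are
#' recoverable from the counts; tumor miRNA columns consequently carry a
#' small global up-shift.
#'
#' @param genes,mirnas Feature tibbles (after [plant_target_sites()]).
#' @param truth The `mir_truth` from [plant_target_sites()].
#' @param config The same [simulation_config()].
#' @return A list with elements `mrna` and `mirna`, each a list of `counts`
#'   (tibble: `feature_id`, `length` for mRNA, one integer column per sample)
#'   and `samples` (tibble: `sample_id`, `pair_id`, `condition`,
#'   `total_clean_reads`, `uniquely_mapped_reads`).
#' @export
simulate_counts <- function(genes, mirnas, truth, config) {
  config <- validate_sim_config(config)
  with_seed(stage_seed(config$rng_seed, "counts"), {
    pair_ids <- sprintf("P%d", seq_len(config$n_pairs))
    draw_matrix <- function(ids, type) {
      n <- length(ids)
      rel <- rlnorm(n, config$baseline_log_mean[1], config$baseline_log_mean[2])
      rel <- pmax(rel, config$min_rel_frac * exp(config$baseline_log_mean[1]))
      if (type == "mirna") {
        # planted miRNAs take below-median abundance ranks so that planting
        # 40 features at FC 4 does not distort the whole composition
        planted <- which(ids %in% c(truth$up_mirna_ids, truth$down_mirna_ids))
        if (length(planted) > 0) {
          rel <- sort(rel)
          low <- seq_len(max(length(planted), floor(n / 2)))
          ranks <- integer(n)
          ranks[planted] <- sample(low, length(planted))
          ranks[-planted] <- sample(setdiff(seq_len(n), ranks[planted]))
          rel <- rel[ranks]
        }
      }
      share <- rel / sum(rel)
      cols <- list()
      meta <- list()
      for (p in pair_ids) {
        eff <- truth$per_pair_effects
        eff <- eff[eff$pair_id == p & eff$feature_type == type, ]
        fc <- setNames(rep(1, n), ids)
        fc[eff$feature_id] <- eff$fc
        # patient-level biological effect, shared by both samples of the pair
        u <- if (config$nb_dispersion > 0) {
          rgamma(n, shape = 1 / config$nb_dispersion, rate = 1 / config$nb_dispersion)
        } else {
          rep(1, n)
        }
        for (cond in c("tumor", "normal")) {
          L <- runif(1, config$library_size_range[1], config$library_size_range[2])
          mu <- L * share * u * (if (cond == "tumor") fc else 1)
          y <- rpois(n, mu)
          sid <- paste0(p, "_", ifelse(cond == "tumor", "T", "N"))
          cols[[sid]] <- as.integer(y)
          meta[[sid]] <- tibble(
            sample_id = sid, pair_id = p, condition = cond,
            total_clean_reads = sum(y), uniquely_mapped_reads = sum(y)
          )
        }
      }
      counts <- tibble(feature_id = ids)
      if (type == "gene") counts$length <- genes$exonic_length
      for (sid in names(cols)) counts[[sid]] <- cols[[sid]]
      list(counts = counts, samples = bind_rows(meta))
    }
    list(
      mrna = draw_matrix(genes$gene_id, "gene"),
      mirna = draw_matrix(mirnas$mirna_id, "mirna")
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_transcriptome()],
#' [generate_mirnome()], [plant_target_sites()] and [simulate_counts()].
#'
#' @param config A [simulation_config()].
#' @return A `mir_cohort` list with `config`, `genes`, `mirnas`, `truth`,
#'   `mrna` and `mirna` (count matrices with sample metadata).
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(
#'   n_genes = 60, n_tfs = 10, n_mirnas = 20, planted_up_mirnas = 5,
#'   hub_site_mirnas = 3, n_target_genes = 5, rng_seed = 1
#' ))
#' glance(co)
simulate_cohort <- function(config = simulation_config()) {
  config <- validate_sim_config(config)
  genes <- generate_transcriptome(config)
  mirnas <- generate_mirnome(config)
  planted <- plant_target_sites(genes, mirnas, config)
  mats <- simulate_counts(planted$genes, mirnas, planted$truth, config)
  structure(list(
    config = config, genes = planted$genes, mirnas = mirnas,
    truth = planted$truth, mrna = mats$mrna, mirna = mats$mirna
  ), class = "mir_cohort")
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat(sprintf(
    "<mir_cohort> %d genes (%d TFs), %d miRNAs, %d pairs; hub %s targeted by %d planted miRNAs\n",
    nrow(x$genes), sum(x$genes$is_tf), nrow(x$mirnas), x$config$n_pairs,
    x$truth$hub_gene_id %||% "<none>",
    sum(x$truth$target_map$gene_id == (x$truth$hub_gene_id %||% ""))
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mir_cohort <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_tfs = sum(x$genes$is_tf),
    n_mirnas = nrow(x$mirnas),
    n_pairs = x$config$n_pairs,
    n_planted_up = length(x$truth$up_mirna_ids),
    n_planted_down = length(x$truth$down_mirna_ids),
    n_target_edges = nrow(x$truth$target_map),
    hub_gene_id = x$truth$hub_gene_id,
    hub_sites = sum(x$truth$target_map$gene_id == (x$truth$hub_gene_id %||% ""))
  )
}

#' @exportS3Method generics::tidy
tidy.mir_truth <- function(x, ...) {
  x$target_map
}
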