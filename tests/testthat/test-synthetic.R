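# Synthetic-cohort generator: determinism, structural invariants, planted
# site soundness, count model behavior, and file round-trips.

test_that("generation is deterministic and respects structural bounds", {
  cfg <- simulation_config(n_genes = 500, n_tfs = 40, n_mirnas = 60,
                           planted_up_mirnas = 10, hub_site_mirnas = 5,
                           n_target_genes = 8, utr_length_range = c(200, 2000),
                           rng_seed = 7)
  g1 <- generate_transcriptome(cfg)
  g2 <- generate_transcriptome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 500)
  expect_equal(sum(g1$is_tf), 40)
  lens <- nchar(g1$utr_seq)
  expect_true(all(lens >= 200 & lens <= 2000))
  expect_false(any(grepl("[^ACGU]", g1$utr_seq)))

  m1 <- generate_mirnome(cfg)
  m2 <- generate_mirnome(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 60)
  expect_true(all(nchar(m1$mature_seq) %in% 19:23))
  seeds_up <- m1$seed[m1$planted_up]
  expect_equal(anyDuplicated(seeds_up), 0)

  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$mrna$counts, co2$mrna$counts)
  expect_identical(co1$truth$target_map, co2$truth$target_map)
})

test_that("zero TFs and invalid configs are handled", {
  cfg0 <- simulation_config(n_genes = 50, n_tfs = 0, n_mirnas = 10,
                            planted_up_mirnas = 0, planted_down_mirnas = 0,
                            hub_site_mirnas = 0, n_target_genes = 3, rng_seed = 3)
  g <- generate_transcriptome(cfg0)
  expect_equal(sum(g$is_tf), 0)
  expect_error(simulation_config(n_pairs = 1), class = "mircoop_config_error")
  expect_error(simulation_config(n_tfs = 10, n_genes = 5), "n_tfs")
  expect_error(simulation_config(hub_site_mirnas = 50, planted_up_mirnas = 10),
               "hub_site_mirnas")
  expect_error(simulation_config(target_suppression_fc = 0.9),
               "target_suppression_fc")
})

test_that("planted sites are exact 8mers rediscovered at recorded positions", {
  cfg <- small_sim_config(seed = 5)
  co <- simulate_cohort(cfg)
  tm <- co$truth$target_map
  expect_gt(nrow(tm), 0)
  hub_rows <- sum(tm$gene_id == co$truth$hub_gene_id)
  expect_equal(hub_rows, cfg$hub_site_mirnas)
  expect_true(co$genes$is_tf[co$genes$gene_id == co$truth$hub_gene_id])

  # 100% recall: every planted entry is found by the site grammar as an 8mer
  found <- vapply(seq_len(nrow(tm)), function(i) {
    utr <- co$genes$utr_seq[co$genes$gene_id == tm$gene_id[i]]
    m <- co$mirnas$mature_seq[co$mirnas$mirna_id == tm$mirna_id[i]]
    s <- find_seed_sites(utr, m)
    any(s$utr_start == tm$utr_start[i] & s$site_type == "8mer")
  }, logical(1))
  expect_true(all(found))

  # no two planted sites of the same gene overlap
  by_gene <- split(tm, tm$gene_id)
  overlaps <- vapply(by_gene, function(d) {
    if (nrow(d) < 2) return(FALSE)
    s <- sort(d$utr_start)
    any(diff(s) < 8)
  }, logical(1))
  expect_false(any(overlaps))

  # every planted (miRNA, gene) passes the default target call
  pass <- vapply(seq_len(min(nrow(tm), 25)), function(i) {
    g <- co$genes[co$genes$gene_id == tm$gene_id[i], ]
    m <- co$mirnas[co$mirnas$mirna_id == tm$mirna_id[i], ]
    sites <- find_target_sites(g, m)
    call_targets(sites, mirna_seq = m$mature_seq)$passes
  }, logical(1))
  expect_true(all(pass))
})

test_that("hub_site_mirnas = 0 leaves UTRs free of planted hub sites", {
  cfg <- simulation_config(n_genes = 80, n_tfs = 10, n_mirnas = 12,
                           planted_up_mirnas = 4, planted_down_mirnas = 0,
                           hub_site_mirnas = 0, n_target_genes = 3,
                           mirnas_per_target = c(2, 3), rng_seed = 2)
  co <- simulate_cohort(cfg)
  expect_false(co$truth$hub_gene_id %in% co$truth$target_map$gene_id)
})

test_that("planted fold change is recoverable from counts in the Poisson limit", {
  # few planted miRNAs so the compositional shift stays inside the tolerance
  fcs <- vapply(1:6, function(seed) {
    cfg <- simulation_config(
      n_genes = 50, n_tfs = 5, n_mirnas = 300, planted_up_mirnas = 5,
      planted_down_mirnas = 0, hub_site_mirnas = 2, n_target_genes = 3,
      mirnas_per_target = c(2, 2), nb_dispersion = 0, background_de_frac = 0,
      rng_seed = seed
    )
    co <- simulate_cohort(cfg)
    cpm <- compute_cpm(co$mirna$counts)
    sm <- co$mirna$samples
    up <- co$truth$up_mirna_ids
    ratios <- vapply(unique(sm$pair_id), function(p) {
      tum <- sm$sample_id[sm$pair_id == p & sm$condition == "tumor"]
      nor <- sm$sample_id[sm$pair_id == p & sm$condition == "normal"]
      mean(cpm[[tum]][cpm$feature_id %in% up] / cpm[[nor]][cpm$feature_id %in% up])
    }, numeric(1))
    mean(ratios)
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 4) / 4, 0.05)
})

test_that("global null construction centres per-feature log-ratios at zero", {
  cfg <- simulation_config(n_genes = 2000, n_tfs = 0, n_mirnas = 20,
                           planted_up_mirnas = 0, planted_down_mirnas = 0,
                           hub_site_mirnas = 0, background_de_frac = 0,
                           rng_seed = 9)
  co <- simulate_cohort(cfg)
  cts <- co$mrna$counts
  lr <- log((cts$P1_T + 0.5) / (cts$P1_N + 0.5)) -
    log(sum(cts$P1_T) / sum(cts$P1_N))
  expect_lt(abs(median(lr)), 0.05)
})

test_that("mRNA column sums stay within the drawn library-size band", {
  cfg <- small_sim_config(seed = 4)
  co <- simulate_cohort(cfg)
  cs <- colSums(co$mrna$counts[setdiff(names(co$mrna$counts), c("feature_id", "length"))])
  expect_true(all(cs >= cfg$library_size_range[1] * 0.8))
  expect_true(all(cs <= cfg$library_size_range[2] * 1.2))
})

test_that("cohorts round-trip losslessly through the plain-text writers", {
  co <- simulate_cohort(small_sim_config(seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$mrna$counts, co$mrna$counts)
  expect_equal(back$mrna$samples$total_clean_reads, co$mrna$samples$total_clean_reads)
  expect_equal(back$mirna$counts, co$mirna$counts)
  expect_equal(back$truth$target_map, co$truth$target_map)
  expect_equal(back$truth$up_mirna_ids, co$truth$up_mirna_ids)
  expect_equal(back$genes$utr_seq, co$genes$utr_seq)
  expect_equal(back$genes$is_tf, co$genes$is_tf)
  # FASTA record count equals n_genes
  fa <- readLines(file.path(dir, "utrs.fasta"))
  expect_equal(sum(startsWith(fa, ">")), nrow(co$genes))
})

test_that("count TSVs with embedded pair/condition header rows are readable", {
  co <- simulate_cohort(small_sim_config(seed = 2))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tsv")
  cts <- co$mrna$counts
  sm <- co$mrna$samples
  scols <- sm$sample_id
  hdr1 <- paste(c("feature_id", "length", scols), collapse = "\t")
  hdr2 <- paste(c("pair_id", "", sm$pair_id[match(scols, sm$sample_id)]), collapse = "\t")
  hdr3 <- paste(c("condition", "", sm$condition[match(scols, sm$sample_id)]), collapse = "\t")
  body <- do.call(paste, c(unname(as.list(cts)), sep = "\t"))
  writeLines(c(hdr1, hdr2, hdr3, body), path)
  got <- read_count_tsv(path)
  expect_equal(got$counts$P1_T, cts$P1_T)
  expect_equal(got$samples$condition[got$samples$sample_id == "P2_N"], "normal")
  expect_equal(got$samples$total_clean_reads[got$samples$sample_id == "P1_T"],
               sum(cts$P1_T))
})
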