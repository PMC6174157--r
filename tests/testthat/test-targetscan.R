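# Target prediction: site grammar against a substring-scan oracle, the
# hybridization aligner against a plain DP oracle, the context-style score
# against direct recomputation, and the gene-level calling rule.

test_that("constructed sites are found with the right type and offset", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"   # 22 nt
  seed27 <- substr(m, 2, 7)
  core7 <- rna_revcomp(substr(m, 2, 8))
  # UTR: 10 nt pad + [m8-complement + core6 + A] + 10 nt pad -> one 8mer at 10
  pad <- "CCCCCCCCCC"
  utr <- paste0(pad, core7, "A", pad)
  sites <- find_seed_sites(utr, m)
  expect_equal(nrow(sites), 1)
  expect_identical(sites$site_type, "8mer")
  expect_equal(sites$utr_start, 10L)

  # same construction without the A1 and without the m8 base
  utr_7m8 <- paste0(pad, core7, "C", pad)
  expect_identical(find_seed_sites(utr_7m8, m)$site_type, "7mer-m8")
  utr_6 <- paste0(pad, "G", substr(core7, 2, 7), "C", pad)
  expect_identical(find_seed_sites(utr_6, m)$site_type, "6mer")
  utr_7a1 <- paste0(pad, "G", substr(core7, 2, 7), "A", pad)
  expect_identical(find_seed_sites(utr_7a1, m)$site_type, "7mer-A1")

  # no complementary 6mer -> empty
  expect_equal(nrow(find_seed_sites("CCCCCCCCCCCCCCCC", m)), 0)
  # T input is normalized, U in seed matching only (no wobble)
  expect_error(find_seed_sites("ACGX", m), class = "mircoop_input_error")
  expect_error(find_seed_sites(utr, "ACGUACGUACGU"), "16")
})

test_that("site grammar equals the naive substring-scan oracle", {
  withr::with_seed(42, {
    utrs <- vapply(1:150, function(i) random_rna_str(300), character(1))
    mirnas <- vapply(1:15, function(i) random_mirna_str(), character(1))
  })
  for (m in mirnas) {
    for (u in utrs[1:40]) {
      got <- find_seed_sites(u, m)
      want <- oracle_seed_scan(u, m)
      expect_equal(got$utr_start, want$utr_start)
      expect_identical(got$site_type, want$site_type)
    }
  }
})

test_that("hybridization score has the documented extremal values", {
  m22 <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_equal(hybrid_align_score(m22, ""), 0)
  expect_equal(hybrid_align_score(m22, rna_revcomp(m22)), 145)
  expect_equal(perfect_duplex_score(m22), 5 * (22 - 7) + 10 * 7)
  m19 <- substr(m22, 1, 19)
  expect_equal(perfect_duplex_score(m19), 5 * 19 + 35)
  expect_error(hybrid_align_score(m22, strrep("A", 81)), "80")
})

test_that("hybridization score equals an independent plain DP oracle", {
  withr::with_seed(7, {
    cases <- lapply(1:60, function(i) {
      list(m = random_mirna_str(), w = random_rna_str(sample(5:30, 1)))
    })
  })
  for (cs in cases) {
    expect_equal(hybrid_align_score(cs$m, cs$w), oracle_align(cs$m, cs$w))
  }
})

test_that("appending matched bases never lowers the alignment optimum", {
  withr::with_seed(19, {
    for (i in 1:10) {
      m <- random_mirna_str()
      w <- random_rna_str(20)
      base <- hybrid_align_score(m, w)
      # append the perfect partner of the miRNA 3' end
      w2 <- paste0(rna_revcomp(m), w)
      expect_gte(hybrid_align_score(m, w2), base)
    }
  })
})

test_that("context-style score matches its closed form", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  core7 <- rna_revcomp(substr(m, 2, 8))
  # centered 6mer in a G/C-only UTR: AU30 = 0, prox = 0 -> -0.03
  core6 <- substr(core7, 2, 7)
  gc_pad <- strrep("G", 60)
  utr <- paste0(gc_pad, core6, gc_pad)   # site exactly centered, length 126
  s <- find_seed_sites(utr, m)
  expect_identical(s$site_type, "6mer")
  expect_equal(context_like_score(utr, s$utr_start, s$site_type), -0.03)

  # 8mer flush against the UTR start in an all-A/U context: -0.31 - 0.1 - 0.1
  site8 <- paste0(core7, "A")
  utr2 <- paste0(site8, strrep("AU", 25))
  expect_equal(context_like_score(utr2, 0L, "8mer"), -0.51)

  # random sites vs direct recomputation
  withr::with_seed(23, {
    for (i in 1:25) {
      u <- random_rna_str(sample(60:200, 1))
      L <- nchar(u)
      type <- sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"), 1)
      len <- c("6mer" = 6, "7mer-A1" = 7, "7mer-m8" = 7, "8mer" = 8)[[type]]
      st <- sample(0:(L - len), 1)
      flank <- paste0(
        substr(u, max(1, st - 29), st),
        substr(u, st + len + 1, min(L, st + len + 30))
      )
      au <- if (nchar(flank) == 0) 0 else
        sum(strsplit(flank, "")[[1]] %in% c("A", "U")) / nchar(flank)
      prox <- max(0, 1 - 2 * min(st, L - st - len) / (L - len))
      base <- c("8mer" = -0.31, "7mer-m8" = -0.16, "7mer-A1" = -0.10, "6mer" = -0.03)[[type]]
      expect_equal(context_like_score(u, st, type), base - 0.1 * au - 0.1 * prox)
    }
  })
  expect_error(context_like_score("ACGUACGU", 5L, "8mer"), class = "mircoop_input_error")
})

test_that("target calling resolves overlaps and applies the dual-threshold rule", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  empty <- call_targets(
    tibble::tibble(gene_id = character(0), mirna_id = character(0),
                   utr_start = integer(0), site_type = character(0),
                   align_score = numeric(0), context_score = numeric(0)),
    mirna_seq = m, gene_id = "g", mirna_id = "mir"
  )
  expect_false(empty$passes)
  expect_equal(empty$n_sites, 0L)

  # two overlapping candidates: the higher-scoring one is retained
  sites <- tibble::tibble(
    gene_id = "g", mirna_id = "mir",
    utr_start = c(10L, 13L), site_type = c("7mer-m8", "8mer"),
    align_score = c(50, 90), context_score = c(-0.2, -0.4)
  )
  call <- call_targets(sites, align_min = 1000)
  expect_equal(call$n_sites, 1L)
  expect_equal(call$total_align_score, 90)
  expect_equal(call$best_context_score, -0.4)
  expect_true(call$passes)  # context branch: negative score with a 7mer+

  # a lone 6mer cannot pass through the context branch
  six <- tibble::tibble(
    gene_id = "g", mirna_id = "mir", utr_start = 5L, site_type = "6mer",
    align_score = 40, context_score = -0.1
  )
  expect_false(call_targets(six, align_min = 1000)$passes)
  # ... but does pass when the alignment branch threshold is reached
  expect_true(call_targets(six, align_min = 40)$passes)

  # mixed ids are rejected
  bad <- sites
  bad$gene_id <- c("g1", "g2")
  expect_error(call_targets(bad, align_min = 10), class = "mircoop_input_error")
})

test_that("call set grows monotonically as thresholds relax", {
  withr::with_seed(31, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:30),
      utr_seq = vapply(1:30, function(i) random_rna_str(400), character(1))
    )
    mirnas <- tibble::tibble(
      mirna_id = sprintf("m%02d", 1:8),
      mature_seq = vapply(1:8, function(i) random_mirna_str(), character(1))
    )
  })
  sites <- find_target_sites(genes, mirnas)
  strict <- call_targets_all(sites, mirnas, align_min_frac = 0.9)
  relaxed <- call_targets_all(sites, mirnas, align_min_frac = 0.5)
  key <- function(x) paste(x$gene_id, x$mirna_id)[x$passes]
  expect_true(all(key(strict) %in% key(relaxed)))
  # raising w_au can only make context scores more negative -> superset
  sites_w <- find_target_sites(genes, mirnas, w_au = 0.3)
  more <- call_targets_all(sites_w, mirnas, align_min_frac = 0.9)
  expect_true(all(key(strict) %in% key(more)))
})
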