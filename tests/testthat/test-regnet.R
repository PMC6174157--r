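# Network assembly: support matching against a brute-force triple loop,
# the recurrence filter, TF subnetwork extraction, hub statistics, exports.

mk_de <- function(ids, pairs, dir_fun) {
  df <- expand.grid(feature_id = ids, pair_id = pairs, stringsAsFactors = FALSE)
  df$direction <- mapply(dir_fun, df$feature_id, df$pair_id)
  tibble::as_tibble(df) |>
    dplyr::mutate(log2_fc = 0, p_value = 0.5, fdr = 0.5, dispersion_used = 0.1)
}

mk_calls <- function(pairs_df) {
  tibble::tibble(
    gene_id = pairs_df$gene_id, mirna_id = pairs_df$mirna_id,
    total_align_score = 10, best_context_score = -0.1, n_sites = 1L,
    passes = pairs_df$passes
  )
}

test_that("edge support is the per-pair intersection of opposite calls", {
  de_m <- mk_de("m1", paste0("P", 1:3), function(f, p) if (p %in% c("P1", "P3")) "up" else "ns")
  de_g <- mk_de("g1", paste0("P", 1:3), function(f, p) if (p %in% c("P1", "P2")) "down" else "ns")
  calls <- mk_calls(data.frame(gene_id = "g1", mirna_id = "m1", passes = TRUE))
  edges <- match_negative_pairs(de_m, de_g, calls)
  expect_equal(nrow(edges), 1)
  expect_identical(edges$pattern, "miR_up_gene_down")
  expect_equal(edges$supporting_pairs[[1]], "P1")
  expect_equal(edges$n_supporting_pairs, 1L)

  # a non-passing call yields no edge regardless of DE
  calls_no <- mk_calls(data.frame(gene_id = "g1", mirna_id = "m1", passes = FALSE))
  expect_equal(nrow(match_negative_pairs(de_m, de_g, calls_no)), 0)

  # unknown ids are an input error
  calls_bad <- mk_calls(data.frame(gene_id = "gX", mirna_id = "m1", passes = TRUE))
  expect_error(match_negative_pairs(de_m, de_g, calls_bad),
               class = "mircoop_input_error")
})

test_that("edge matching equals a brute-force triple loop on random fixtures", {
  withr::with_seed(77, {
    mir_ids <- sprintf("m%02d", 1:12)
    gene_ids <- sprintf("g%02d", 1:20)
    pairs <- paste0("P", 1:4)
    de_m <- mk_de(mir_ids, pairs, function(f, p) sample(c("up", "down", "ns"), 1))
    de_g <- mk_de(gene_ids, pairs, function(f, p) sample(c("up", "down", "ns"), 1))
    combos <- expand.grid(gene_id = gene_ids, mirna_id = mir_ids,
                          stringsAsFactors = FALSE)
    combos$passes <- sample(c(TRUE, FALSE), nrow(combos), replace = TRUE)
  })
  calls <- mk_calls(combos)
  edges <- match_negative_pairs(de_m, de_g, calls)

  # oracle: explicit loops over (miRNA, gene, pair)
  want <- list()
  for (m in mir_ids) for (g in gene_ids) {
    if (!combos$passes[combos$gene_id == g & combos$mirna_id == m]) next
    for (pat in c("miR_up_gene_down", "miR_down_gene_up")) {
      md <- if (pat == "miR_up_gene_down") "up" else "down"
      gd <- if (pat == "miR_up_gene_down") "down" else "up"
      supp <- character(0)
      for (p in pairs) {
        if (de_m$direction[de_m$feature_id == m & de_m$pair_id == p] == md &&
            de_g$direction[de_g$feature_id == g & de_g$pair_id == p] == gd) {
          supp <- c(supp, p)
        }
      }
      if (length(supp) > 0) {
        want[[paste(m, g, pat)]] <- supp
      }
    }
  }
  expect_equal(nrow(edges), length(want))
  got_keys <- paste(edges$mirna_id, edges$gene_id, edges$pattern)
  expect_setequal(got_keys, names(want))
  for (i in seq_len(nrow(edges))) {
    expect_equal(edges$supporting_pairs[[i]], sort(want[[got_keys[i]]]))
  }
})

test_that("recurrence filter keeps >= min_pairs and is monotone", {
  edges <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3"), gene_id = "g1",
    pattern = "miR_up_gene_down",
    supporting_pairs = list("P1", c("P1", "P2"), c("P1", "P2", "P3")),
    n_supporting_pairs = c(1L, 2L, 3L)
  )
  expect_equal(nrow(apply_recurrence_filter(edges, 2)), 2)
  expect_identical(apply_recurrence_filter(edges, 1), edges)
  expect_error(apply_recurrence_filter(edges, 0), class = "mircoop_input_error")
  for (mp in 3:1) {
    hi <- apply_recurrence_filter(edges, mp)
    lo <- apply_recurrence_filter(edges, max(mp - 1, 1))
    expect_true(all(hi$mirna_id %in% lo$mirna_id))
  }
})

test_that("TF subnetwork keeps only the requested pattern and TF genes", {
  edges <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2"), gene_id = c("g1", "g2", "g1"),
    pattern = c("miR_up_gene_down", "miR_up_gene_down", "miR_down_gene_up"),
    supporting_pairs = list(c("P1", "P2"), c("P1", "P2"), c("P1", "P2")),
    n_supporting_pairs = 2L
  )
  net <- build_tf_subnetwork(edges, tf_ids = "g1")
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes$id, c("m1", "g1"))
  empty <- build_tf_subnetwork(edges, tf_ids = "gZ")
  expect_equal(nrow(empty$edges), 0)
  # node set is exactly the endpoints of retained edges
  expect_setequal(net$nodes$id, c(net$edges$mirna_id, net$edges$gene_id))
})

test_that("hub statistics count exact degrees in deterministic order", {
  expect_equal(nrow(hub_statistics(build_tf_subnetwork(
    tibble::tibble(mirna_id = character(0), gene_id = character(0),
                   pattern = character(0), supporting_pairs = list(),
                   n_supporting_pairs = integer(0)), "g1"))), 0)
  edges <- tibble::tibble(
    mirna_id = c("m1", "m2", "m1"), gene_id = c("g1", "g1", "g2"),
    pattern = "miR_up_gene_down",
    supporting_pairs = list("P1", "P1", "P1"), n_supporting_pairs = 1L
  )
  hs <- hub_statistics(as_mir_network(edges, tf_ids = "g1"))
  expect_equal(hs$degree[hs$id == "g1"], 2)
  expect_equal(hs$degree[hs$id == "g2"], 1)
  expect_equal(hs$degree[hs$id == "m1"], 2)
  expect_equal(hs$degree[hs$id == "m2"], 1)
  expect_equal(hs$id[1:2], c("g1", "m1"))  # ties broken by id
})

test_that("edge lists export to SIF and round-trip through TSV", {
  edges <- tibble::tibble(
    mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
    pattern = "miR_up_gene_down",
    supporting_pairs = list(c("P1", "P3"), c("P2", "P4")),
    n_supporting_pairs = 2L
  )
  net <- as_mir_network(edges, tf_ids = "g1", min_pairs = 2L)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_edge_list(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 2)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  expect_true(all(lengths(fields) == 3))
  expect_true(all(vapply(fields, `[`, character(1), 2) == "represses"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(net, tsv, "tsv")
  back <- read_edge_list(tsv)
  expect_equal(back$mirna_id, edges$mirna_id)
  expect_equal(back$supporting_pairs, edges$supporting_pairs)
  expect_equal(back$n_supporting_pairs, edges$n_supporting_pairs)

  expect_error(export_edge_list(net, file.path(tempdir(), "no", "dir", "x.tsv")),
               class = "mircoop_io_error")
})

test_that("tidy and glance summarize networks consistently", {
  edges <- tibble::tibble(
    mirna_id = "m1", gene_id = "g1", pattern = "miR_up_gene_down",
    supporting_pairs = list(c("P1", "P2")), n_supporting_pairs = 2L
  )
  net <- as_mir_network(edges, tf_ids = "g1", min_pairs = 2L)
  td <- generics::tidy(net)
  expect_identical(td$supporting_pairs, "P1,P2")
  gl <- generics::glance(net)
  expect_equal(gl$n_edges, 1)
  expect_equal(gl$n_tfs, 1)
})
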