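# Plain-text persistence of a synthetic cohort: FASTA for sequences, TSV for
# counts and sample metadata, a GMT-like file for the GO map, JSON for the
# planted truth and the generator config. Everything round-trips losslessly
# through read_cohort().

#' Write a count matrix with sample metadata as TSV
#'
#' The counts file carries `feature_id` (and `length` for mRNA) plus one
#' integer column per sample; metadata goes to a sibling `*_samples.tsv`.
#'
#' @param counts Count tibble (`feature_id`, optional `length`, sample columns).
#' @param samples Sample metadata tibble.
#' @param path Path of the counts TSV; metadata is written next to it.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(counts, samples, path) {
  tryCatch({
    readr::write_tsv(counts, path)
    readr::write_tsv(samples, samples_path(path))
  }, error = function(e) io_error(sprintf("failed to write '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

samples_path <- function(path) sub("\\.tsv$", "_samples.tsv", path)

#' Read a count matrix with sample metadata
#'
#' Supports the two layouts written/accepted by the package: a counts TSV
#' with a sibling `*_samples.tsv`, or a counts TSV whose second and third
#' header rows carry `pair_id` and `condition` (in which case read totals
#' default to the column sums).
#'
#' @param path Path of the counts TSV.
#' @return A list with `counts` and `samples` tibbles.
#' @export
read_count_tsv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("count file '%s' does not exist", path))
  sp <- samples_path(path)
  if (file.exists(sp)) {
    counts <- readr::read_tsv(path, show_col_types = FALSE)
    samples <- readr::read_tsv(sp, show_col_types = FALSE)
    return(list(counts = counts, samples = samples))
  }
  # embedded-header layout: rows 2 and 3 hold pair_id / condition
  hdr <- readr::read_tsv(path, n_max = 2, show_col_types = FALSE)
  counts <- readr::read_tsv(path, skip = 3, col_names = names(hdr), show_col_types = FALSE)
  scols <- setdiff(names(counts), c("feature_id", "length"))
  counts <- counts |> mutate(across(dplyr::all_of(scols), as.integer))
  samples <- tibble(
    sample_id = scols,
    pair_id = as.character(unlist(hdr[1, scols])),
    condition = as.character(unlist(hdr[2, scols])),
    total_clean_reads = unname(vapply(scols, function(s) sum(counts[[s]]), numeric(1))),
    uniquely_mapped_reads = unname(vapply(scols, function(s) sum(counts[[s]]), numeric(1)))
  )
  list(counts = counts, samples = samples)
}

write_fasta <- function(seqs, ids, path) {
  x <- Biostrings::RNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_fasta_rna <- function(path) {
  if (!file.exists(path)) io_error(sprintf("FASTA file '%s' does not exist", path))
  x <- Biostrings::readBStringSet(path)
  setNames(normalize_rna(as.character(x)), names(x))
}

#' Read/write a GMT-like term map
#'
#' One term per line: `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param terms Long tibble with `term_id`, `term_name`, `gene_id`.
#' @param path File path.
#' @return `read_gmt()` returns the long tibble; `write_gmt()` the path.
#' @export
write_gmt <- function(terms, path) {
  lines <- terms |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(genes = paste(.data$gene_id, collapse = "\t"), .groups = "drop") |>
    arrange(.data$term_id)
  writeLines(paste(lines$term_id, lines$term_name, lines$genes, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("GMT file '%s' does not exist", path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  purrr::map(parts, function(p) {
    tibble(term_id = p[1], term_name = p[2], gene_id = p[-(1:2)])
  }) |> list_rbind()
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits UTR and miRNA FASTA, the two count TSVs with sample metadata, a TF
#' list TSV, a GMT-like GO map, the planted truth as JSON and the generator
#' config as JSON. The file set round-trips through [read_cohort()].
#'
#' @param cohort A `mir_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) io_error(sprintf("cannot create output directory '%s'", outdir))
  }
  p <- function(f) file.path(outdir, f)
  write_fasta(cohort$genes$utr_seq, cohort$genes$gene_id, p("utrs.fasta"))
  write_fasta(cohort$mirnas$mature_seq, cohort$mirnas$mirna_id, p("mirnas.fasta"))
  write_count_tsv(cohort$mrna$counts, cohort$mrna$samples, p("mrna_counts.tsv"))
  write_count_tsv(cohort$mirna$counts, cohort$mirna$samples, p("mirna_counts.tsv"))
  readr::write_tsv(cohort$genes |> filter(.data$is_tf) |> select("gene_id"), p("tf_list.tsv"))
  readr::write_tsv(
    cohort$mirnas |> select("mirna_id", "planted_up", "planted_down"),
    p("mirna_flags.tsv")
  )
  write_gmt(go_term_map(cohort$genes), p("go_map.gmt"))
  truth <- cohort$truth
  jsonlite::write_json(list(
    up_mirna_ids = truth$up_mirna_ids,
    down_mirna_ids = truth$down_mirna_ids,
    hub_gene_id = truth$hub_gene_id,
    target_map = truth$target_map,
    per_pair_effects = truth$per_pair_effects
  ), p("truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cohort$config), p("config.json"), auto_unbox = FALSE, digits = NA)
  invisible(outdir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `mir_cohort` list.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  utrs <- read_fasta_rna(p("utrs.fasta"))
  mir_seqs <- read_fasta_rna(p("mirnas.fasta"))
  mrna <- read_count_tsv(p("mrna_counts.tsv"))
  mirna <- read_count_tsv(p("mirna_counts.tsv"))
  tf <- readr::read_tsv(p("tf_list.tsv"), show_col_types = FALSE)
  flags <- readr::read_tsv(p("mirna_flags.tsv"), show_col_types = FALSE)
  go <- read_gmt(p("go_map.gmt"))
  tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  cfgj <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  config <- do.call(simulation_config, cfgj[setdiff(names(cfgj), character(0))])
  genes <- tibble(
    gene_id = names(utrs), utr_seq = unname(utrs),
    exonic_length = mrna$counts$length[match(names(utrs), mrna$counts$feature_id)],
    is_tf = names(utrs) %in% tf$gene_id,
    go_terms = purrr::map(names(utrs), function(g) sort(go$term_id[go$gene_id == g]))
  )
  mirnas <- tibble(
    mirna_id = names(mir_seqs), mature_seq = unname(mir_seqs),
    seed = str_sub(unname(mir_seqs), 2, 8),
    planted_up = flags$planted_up[match(names(mir_seqs), flags$mirna_id)],
    planted_down = flags$planted_down[match(names(mir_seqs), flags$mirna_id)]
  )
  tm <- as_tibble(tj$target_map)
  tm$utr_start <- as.integer(tm$utr_start)
  truth <- structure(list(
    up_mirna_ids = as.character(tj$up_mirna_ids %||% character(0)),
    down_mirna_ids = as.character(tj$down_mirna_ids %||% character(0)),
    target_map = tm,
    hub_gene_id = tj$hub_gene_id,
    per_pair_effects = as_tibble(tj$per_pair_effects)
  ), class = "mir_truth")
  structure(list(
    config = config, genes = genes, mirnas = mirnas, truth = truth,
    mrna = mrna, mirna = mirna
  ), class = "mir_cohort")
}
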