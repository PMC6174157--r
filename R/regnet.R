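# Assembly of the negative miRNA-mRNA regulatory network: sign-opposite
# significant DE within the same tumor/normal pair certifies an interaction
# for each passing target call; edges recurring in at least `min_pairs`
# pairs are retained; the up-miRNA / down-TF subnetwork and hub statistics
# summarize cooperative suppression.

edge_prototype <- function() {
  tibble(
    mirna_id = character(0), gene_id = character(0), pattern = character(0),
    supporting_pairs = list(), n_supporting_pairs = integer(0)
  )
}

#' Match passing target calls with sign-opposite DE
#'
#' For each passing (miRNA, gene) target call and each pair, adds the pair as
#' support for pattern `miR_up_gene_down` when the miRNA is called up and the
#' gene down in that pair (and symmetrically for `miR_down_gene_up`). Edges
#' with no supporting pair are omitted; mixed patterns across pairs yield two
#' separate edges.
#'
#' @param de_mirna,de_mrna Multi-pair DE tibbles from [run_de()].
#' @param target_calls Call tibble from [call_targets_all()].
#' @return An unfiltered edge tibble: `mirna_id`, `gene_id`, `pattern`,
#'   `supporting_pairs` (list column), `n_supporting_pairs`.
#' @export
match_negative_pairs <- function(de_mirna, de_mrna, target_calls) {
  calls <- target_calls[target_calls$passes, c("mirna_id", "gene_id")]
  if (nrow(calls) == 0) return(edge_prototype())
  unknown_m <- setdiff(calls$mirna_id, de_mirna$feature_id)
  unknown_g <- setdiff(calls$gene_id, de_mrna$feature_id)
  if (length(unknown_m) > 0 || length(unknown_g) > 0) {
    input_error(paste(
      "target_calls contain ids absent from the DE tables:",
      paste(head(c(unknown_m, unknown_g), 5), collapse = ", ")
    ))
  }
  mdir <- de_mirna |> select(mirna_id = "feature_id", "pair_id", m_dir = "direction")
  gdir <- de_mrna |> select(gene_id = "feature_id", "pair_id", g_dir = "direction")
  support <- calls |>
    inner_join(mdir, by = "mirna_id", relationship = "many-to-many") |>
    inner_join(gdir, by = c("gene_id", "pair_id"), relationship = "many-to-many") |>
    mutate(pattern = dplyr::case_when(
      .data$m_dir == "up" & .data$g_dir == "down" ~ "miR_up_gene_down",
      .data$m_dir == "down" & .data$g_dir == "up" ~ "miR_down_gene_up",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$pattern))
  if (nrow(support) == 0) return(edge_prototype())
  support |>
    group_by(.data$mirna_id, .data$gene_id, .data$pattern) |>
    summarise(supporting_pairs = list(sort(unique(.data$pair_id))), .groups = "drop") |>
    mutate(n_supporting_pairs = map_int(.data$supporting_pairs, length)) |>
    arrange(.data$mirna_id, .data$gene_id, .data$pattern)
}

#' Recurrence filter on interaction edges
#'
#' Keeps edges supported by at least `min_pairs` tumor/normal pairs; retained
#' edges are unmodified.
#'
#' @param edges Edge tibble from [match_negative_pairs()].
#' @param min_pairs Minimum number of supporting pairs (default 2).
#' @return The filtered edge tibble.
#' @export
apply_recurrence_filter <- function(edges, min_pairs = 2) {
  if (min_pairs < 1) input_error("min_pairs must be >= 1")
  edges[edges$n_supporting_pairs >= min_pairs, ]
}

#' Construct a bipartite regulatory network from edges
#'
#' @param edges Edge tibble.
#' @param tf_ids Character vector of TF gene ids (used to flag gene nodes).
#' @param min_pairs The recurrence filter already applied (recorded only).
#' @return A `mir_network`: list of `nodes` (id, role, is_tf), `edges`,
#'   `min_pairs`.
#' @export
as_mir_network <- function(edges, tf_ids = character(0), min_pairs = NA_integer_) {
  nodes <- bind_rows(
    tibble(id = unique(edges$mirna_id), role = "miRNA", is_tf = FALSE),
    tibble(id = unique(edges$gene_id), role = "gene") |>
      mutate(is_tf = .data$id %in% tf_ids)
  )
  structure(list(nodes = nodes, edges = edges, min_pairs = min_pairs),
            class = "mir_network")
}

#' Up-miRNA / down-TF subnetwork
#'
#' Restricts a network (or edge tibble) to edges of the given pattern whose
#' gene is a TF; isolated nodes are dropped.
#'
#' @param network A `mir_network` or an edge tibble.
#' @param tf_ids Character vector of TF gene ids.
#' @param pattern Edge pattern to keep (default `"miR_up_gene_down"`).
#' @return A `mir_network` restricted to the TF subnetwork.
#' @export
build_tf_subnetwork <- function(network, tf_ids, pattern = "miR_up_gene_down") {
  edges <- if (inherits(network, "mir_network")) network$edges else network
  min_pairs <- if (inherits(network, "mir_network")) network$min_pairs else NA_integer_
  sub <- edges[edges$pattern == pattern & edges$gene_id %in% tf_ids, ]
  as_mir_network(sub, tf_ids = tf_ids, min_pairs = min_pairs)
}

#' Hub statistics of a regulatory network
#'
#' Exact node degrees: for genes the number of targeting miRNAs, for miRNAs
#' the number of targeted genes, in a deterministic order (degree descending,
#' id ascending).
#'
#' @param network A `mir_network` or an edge tibble.
#' @return A tibble with `id`, `role`, `is_tf`, `degree`.
#' @export
hub_statistics <- function(network) {
  net <- if (inherits(network, "mir_network")) network else as_mir_network(network)
  if (nrow(net$edges) == 0) {
    return(tibble(id = character(0), role = character(0), is_tf = logical(0),
                  degree = integer(0)))
  }
  deg <- bind_rows(
    net$edges |> count(id = .data$gene_id, name = "degree"),
    net$edges |> count(id = .data$mirna_id, name = "degree")
  )
  net$nodes |>
    inner_join(deg, by = "id") |>
    arrange(desc(.data$degree), .data$id)
}

#' Export a network edge list
#'
#' `sif` writes Cytoscape SIF lines `mirna<TAB>represses<TAB>gene`; `tsv`
#' adds pattern and supporting-pair information and round-trips through
#' [read_edge_list()].
#'
#' @param network A `mir_network` or edge tibble.
#' @param path File path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- if (inherits(network, "mir_network")) network$edges else network
  ok <- tryCatch({
    if (format == "sif") {
      writeLines(paste(edges$mirna_id, "represses", edges$gene_id, sep = "\t"), path)
    } else {
      readr::write_tsv(tidy_edges(edges), path)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("failed to write edge list to '%s'", path))
  invisible(path)
}

tidy_edges <- function(edges) {
  edges |>
    mutate(supporting_pairs = map_chr(.data$supporting_pairs, paste, collapse = ",")) |>
    select("mirna_id", "gene_id", "pattern", "n_supporting_pairs", "supporting_pairs")
}

#' Re-import an edge-list TSV written by [export_edge_list()]
#'
#' @param path File path.
#' @return An edge tibble with the `supporting_pairs` list column restored.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) io_error(sprintf("edge list '%s' does not exist", path))
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(
      supporting_pairs = map(str_split(.data$supporting_pairs, ","), sort),
      n_supporting_pairs = as.integer(.data$n_supporting_pairs)
    ) |>
    select("mirna_id", "gene_id", "pattern", "supporting_pairs", "n_supporting_pairs")
}

#' Write node attributes (id, role, is_tf) as TSV
#'
#' @param network A `mir_network`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(network, path) {
  readr::write_tsv(network$nodes, path)
  invisible(path)
}

#' @export
print.mir_network <- function(x, ...) {
  cat(sprintf(
    "<mir_network> %d miRNAs, %d genes (%d TFs), %d edges (min_pairs = %s)\n",
    sum(x$nodes$role == "miRNA"), sum(x$nodes$role == "gene"),
    sum(x$nodes$is_tf), nrow(x$edges), x$min_pairs
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mir_network <- function(x, ...) {
  tidy_edges(x$edges)
}

#' @exportS3Method generics::glance
glance.mir_network <- function(x, ...) {
  tibble(
    n_mirnas = sum(x$nodes$role == "miRNA"),
    n_genes = sum(x$nodes$role == "gene"),
    n_tfs = sum(x$nodes$is_tf),
    n_edges = nrow(x$edges),
    min_pairs = x$min_pairs
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_network <- function(object, top = 20, ...) {
  stats <- hub_statistics(object) |>
    filter(.data$role == "gene") |>
    slice_head(n = top)
  ggplot2::ggplot(stats, ggplot2::aes(
    x = stats::reorder(.data$id, .data$degree), y = .data$degree, fill = .data$is_tf
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "targeting miRNAs", fill = "TF") +
    ggplot2::theme_minimal()
}
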