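# Term enrichment of gene sets: central hypergeometric upper-tail test by
# default, Wallenius non-central hypergeometric (exact recursive PMF, Monte
# Carlo for large universes) when gene weights are supplied, BH correction
# across tested terms, and the rich factor k/K reported per term.

coerce_terms <- function(terms) {
  if (is.data.frame(terms)) {
    if (!all(c("term_id", "gene_id") %in% names(terms))) {
      input_error("terms data frame needs 'term_id' and 'gene_id' columns")
    }
    if (!"term_name" %in% names(terms)) terms$term_name <- terms$term_id
    return(terms[c("term_id", "term_name", "gene_id")])
  }
  if (is.list(terms)) {
    return(purrr::imap(terms, function(g, id) {
      tibble(term_id = id, term_name = id, gene_id = g)
    }) |> list_rbind())
  }
  input_error("terms must be a long data frame or a named list of gene sets")
}

enrich_scaffold <- function(study_set, universe, terms) {
  study_set <- unique(study_set)
  universe <- unique(universe)
  outside <- setdiff(study_set, universe)
  if (length(outside) > 0) {
    input_error(paste(
      "study genes outside the universe:", paste(head(outside, 5), collapse = ", ")
    ))
  }
  tm <- coerce_terms(terms) |> filter(.data$gene_id %in% universe)
  rows <- tm |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(intersect(.data$gene_id, study_set)),
      genes = list(unique(.data$gene_id)),
      .groups = "drop"
    ) |>
    filter(.data$K >= 1, .data$k >= 1) |>
    mutate(n = length(study_set), N = length(universe))
  rows
}

finish_enrichment <- function(rows) {
  rows <- rows |>
    mutate(fdr = bh_adjust(.data$p_value), rich_factor = .data$k / .data$K) |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_value", "fdr", "rich_factor") |>
    arrange(.data$p_value, .data$term_id)
  class(rows) <- c("mir_enrichment", class(rows))
  rows
}

#' Hypergeometric term enrichment
#'
#' Upper-tail (at least k hits) central hypergeometric test per term, with
#' term gene sets intersected with the universe first; terms with no
#' universe genes or no study hits are excluded before BH correction. The
#' rich factor is k/K, the fraction of a term's genes present in the study
#' set.
#'
#' @param study_set Character vector of study genes (must lie in `universe`).
#' @param universe Character vector of background genes.
#' @param terms Long tibble (`term_id`, `term_name`, `gene_id`) or named list
#'   of gene-id vectors.
#' @return A `mir_enrichment` tibble: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_value`, `fdr`, `rich_factor`, sorted by p then term id.
#' @export
hypergeom_enrich <- function(study_set, universe, terms) {
  rows <- enrich_scaffold(study_set, universe, terms)
  rows$p_value <- phyper(rows$k - 1, rows$K, rows$N - rows$K, rows$n, lower.tail = FALSE)
  finish_enrichment(rows)
}

# Wallenius non-central hypergeometric upper tail P(X >= k) for n sequential
# weighted draws without replacement from K "term" genes with odds `omega`
# against N-K others. Exact O(n^2) forward recursion on the draw count.
wallenius_upper_tail <- function(k, K, n, N, omega) {
  if (k <= 0) return(1)
  kmax <- min(K, n)
  if (k > kmax) return(0)
  prob <- c(1, rep(0, kmax))  # P(X_j = x), x = 0..kmax, starting at j = 0
  for (j in seq_len(n)) {
    x <- 0:min(j - 1, kmax)
    denom <- (K - x) * omega + (N - K - (j - 1 - x))
    take <- prob[x + 1] * ifelse(denom > 0, (K - x) * omega / denom, 0)
    stay <- prob[x + 1] * ifelse(denom > 0, (N - K - (j - 1 - x)) / denom, 0)
    nxt <- rep(0, kmax + 1)
    nxt[x + 1] <- nxt[x + 1] + stay
    shifted <- x + 2
    ok <- shifted <= kmax + 1
    nxt[shifted[ok]] <- nxt[shifted[ok]] + take[ok]
    prob <- nxt
  }
  sum(prob[(k + 1):(kmax + 1)])
}

# Monte-Carlo fallback for very large universes: sequential weighted draws
# without replacement are exactly the Wallenius sampling scheme.
wallenius_mc_tail <- function(k, K, n, N, omega, draws = 1e5, seed = 505L) {
  w <- c(rep(omega, K), rep(1, N - K))
  with_seed(seed, {
    hits <- vapply(seq_len(draws), function(i) {
      sum(sample.int(N, n, prob = w) <= K)
    }, numeric(1))
  })
  mean(hits >= k)
}

#' Wallenius non-central hypergeometric enrichment
#'
#' Like [hypergeom_enrich()] but with biased sampling: each term's odds are
#' `omega = mean(weight[term genes]) / mean(weight[other genes])`. The PMF is
#' computed by exact recursion for universes up to 2000 genes and by Monte
#' Carlo (1e5 weighted draws, fixed internal seed) beyond. Uniform weights
#' reproduce the central test.
#'
#' @inheritParams hypergeom_enrich
#' @param weights Named positive numeric vector of gene weights covering the
#'   universe (unnamed weights of length `length(universe)` are accepted).
#' @return A `mir_enrichment` tibble.
#' @export
wallenius_enrich <- function(study_set, universe, terms, weights) {
  universe <- unique(universe)
  if (is.null(names(weights))) {
    if (length(weights) != length(universe)) {
      input_error("unnamed weights must have one entry per universe gene")
    }
    weights <- setNames(weights, universe)
  }
  w <- weights[universe]
  if (any(is.na(w)) || any(w <= 0)) input_error("weights must be positive for every universe gene")
  rows <- enrich_scaffold(study_set, universe, terms)
  rows$p_value <- pmap(
    list(rows$k, rows$K, rows$n, rows$genes),
    function(k, K, n, genes) {
      N <- length(universe)
      omega <- mean(w[genes]) / mean(w[setdiff(universe, genes)])
      if (K == N) return(1)  # degenerate: every draw is a term gene
      if (N <= 2000) wallenius_upper_tail(k, K, n, N, omega)
      else wallenius_mc_tail(k, K, n, N, omega)
    }
  ) |> unlist()
  finish_enrichment(rows)
}

#' Top enriched terms
#'
#' The `k` rows with smallest p-value, ties broken by term id; returns all
#' rows when `k` exceeds the table size.
#'
#' @param rows A `mir_enrichment` tibble.
#' @param k Number of terms (default 15).
#' @return The selected rows.
#' @export
top_terms <- function(rows, k = 15) {
  rows |> arrange(.data$p_value, .data$term_id) |> slice_head(n = k)
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_enrichment <- function(object, top = 15, ...) {
  df <- top_terms(object, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rich_factor,
    y = stats::reorder(.data$term_name, -.data$p_value),
    size = .data$k, colour = .data$fdr
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#c0392b", high = "#2980b9") +
    ggplot2::labs(x = "rich factor (k/K)", y = NULL, size = "genes", colour = "FDR") +
    ggplot2::theme_minimal()
}
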