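# Per-pair differential expression for designs without replicates: an exact
# conditional test on negative-binomial counts at a supplied dispersion,
# CPM-based fold changes, Benjamini-Hochberg FDR within each pair, and
# cross-pair recurrence/coordination summaries.

# Two-sided conditional p-value given the equalized split (ya, s - ya).
# Conditional on the total s, two iid NB(mu = s/2, size = 1/phi) counts give
# split weights w(i) = NB(i) * NB(s - i); these are accumulated as cumulative
# log-ratios, which is numerically stable for any dispersion including the
# Poisson limit (phi -> 0, where the conditional law is Binomial(s, 1/2)).
nb_cond_pvalue <- function(ya, s, phi) {
  if (s == 0) return(1)
  i <- 0:(s - 1)
  lr <- if (phi <= 0) {
    log(s - i) - log(i + 1)
  } else {
    r <- 1 / phi
    log(i + r) + log(s - i) - log(i + 1) - log(s - i - 1 + r)
  }
  lw <- c(0, cumsum(lr))
  sel <- lw <= lw[ya + 1] + log1p(1e-9)  # tie tolerance on the weight scale
  m <- max(lw)
  sum(exp(lw[sel] - m)) / sum(exp(lw - m))
}

#' Exact negative-binomial test for a 1-vs-1 comparison
#'
#' Counts are first equalized to a common library size (the geometric mean of
#' the two library sizes) by scaling and rounding half-to-even. Conditional
#' on the equalized total `s`, each split receives the weight
#' `NB(i; mu = s/2, phi) * NB(s - i; mu = s/2, phi)` and the two-sided
#' p-value sums the weights not exceeding the observed one (with a `1e-9`
#' relative tie tolerance). As `phi -> 0` the test reduces to the exact
#' two-tailed Binomial(s, 1/2) test.
#'
#' @param count_a,count_b Observed counts (non-negative integers).
#' @param lib_a,lib_b Library sizes (positive).
#' @param dispersion NB dispersion phi (>= 0); 0 gives the Poisson limit.
#' @return A p-value in (0, 1].
#' @export
#' @examples
#' nb_exact_test(0, 10, 1e6, 1e6, 1e-8)  # ~ 2 * 2^-10
nb_exact_test <- function(count_a, count_b, lib_a, lib_b, dispersion) {
  if (count_a < 0 || count_b < 0) input_error("counts must be non-negative")
  if (lib_a <= 0 || lib_b <= 0) input_error("library sizes must be positive")
  if (dispersion < 0) input_error("dispersion must be >= 0")
  ls <- sqrt(lib_a * lib_b)
  ya <- round(count_a * ls / lib_a)
  yb <- round(count_b * ls / lib_b)
  nb_cond_pvalue(ya, ya + yb, dispersion)
}

#' Log2 fold change with a pseudocount
#'
#' `log2((x_tumor + c) / (x_normal + c))`; antisymmetric under swapping the
#' two conditions.
#'
#' @param cpm_tumor,cpm_normal Non-negative expression values (typically CPM).
#' @param pseudocount Positive stabilizer (default 0.5).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(cpm_tumor, cpm_normal, pseudocount = 0.5) {
  if (pseudocount <= 0) input_error("pseudocount must be positive")
  if (any(cpm_tumor < 0) || any(cpm_normal < 0)) input_error("expression values must be >= 0")
  log2((cpm_tumor + pseudocount) / (cpm_normal + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted values, each in `[p, 1]`.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    input_error("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

de_direction <- function(log2_fc, fdr, fc_threshold, fdr_threshold) {
  lfc <- log2(fc_threshold)
  dplyr::case_when(
    log2_fc > lfc & fdr < fdr_threshold ~ "up",
    log2_fc < -lfc & fdr < fdr_threshold ~ "down",
    TRUE ~ "ns"
  )
}

#' Differential expression for one tumor/normal pair
#'
#' Features are pre-filtered by the CPM rule (CPM above `cpm_threshold` in at
#' least `cpm_min_samples` of all samples), tested with [nb_exact_test()] at
#' the supplied dispersion using column totals as library sizes, BH-adjusted
#' across all retained features within the pair, and called `up`/`down` when
#' `|fold change| > fc_threshold` and `fdr < fdr_threshold`.
#'
#' @param counts Count tibble (`feature_id`, optional `length`, sample columns).
#' @param samples Sample metadata with `sample_id`, `pair_id`, `condition`.
#' @param pair_id The pair to test.
#' @param dispersion NB dispersion used for every feature (default 0.1, a
#'   conservative choice for designs without replicates).
#' @param fc_threshold,fdr_threshold Calling rule (defaults 1.5 and 0.05).
#' @param cpm_threshold,cpm_min_samples Expression filter (defaults 1 and 1,
#'   strict `>` comparison).
#' @return A tibble with `feature_id`, `pair_id`, `log2_fc`, `p_value`,
#'   `fdr`, `direction`, `dispersion_used`.
#' @export
run_pair_de <- function(counts, samples, pair_id, dispersion = 0.1,
                        fc_threshold = 1.5, fdr_threshold = 0.05,
                        cpm_threshold = 1, cpm_min_samples = 1) {
  parts <- count_parts(counts)
  sm <- samples[samples$pair_id == pair_id, ]
  tum <- sm$sample_id[sm$condition == "tumor"]
  nor <- sm$sample_id[sm$condition == "normal"]
  if (length(tum) != 1 || length(nor) != 1) {
    input_error(sprintf("pair '%s' must have exactly one tumor and one normal sample", pair_id))
  }
  keep <- filter_expressed(compute_cpm(counts), cpm_threshold, cpm_min_samples, ">")
  if (length(keep) == 0) {
    return(tibble(
      feature_id = character(), pair_id = character(), log2_fc = numeric(),
      p_value = numeric(), fdr = numeric(), direction = character(),
      dispersion_used = numeric()
    ))
  }
  lib <- colSums(parts$mat)
  ya <- unname(parts$mat[keep, tum])
  yb <- unname(parts$mat[keep, nor])
  ls <- sqrt(lib[tum] * lib[nor])
  ya_eq <- round(ya * ls / lib[tum])
  yb_eq <- round(yb * ls / lib[nor])
  p <- vapply(seq_along(ya_eq), function(i) {
    nb_cond_pvalue(ya_eq[i], ya_eq[i] + yb_eq[i], dispersion)
  }, numeric(1))
  cpm_t <- ya / lib[tum] * 1e6
  cpm_n <- yb / lib[nor] * 1e6
  lfc <- log2_fold_change(cpm_t, cpm_n)
  fdr <- bh_adjust(p)
  tibble(
    feature_id = keep, pair_id = pair_id, log2_fc = lfc, p_value = p,
    fdr = fdr,
    direction = de_direction(lfc, fdr, fc_threshold, fdr_threshold),
    dispersion_used = dispersion
  )
}

#' Differential expression across all pairs
#'
#' Runs [run_pair_de()] for every pair in `samples` and binds the results.
#'
#' @inheritParams run_pair_de
#' @param ... Passed to [run_pair_de()].
#' @return A tibble of per-pair DE rows.
#' @export
run_de <- function(counts, samples, ...) {
  pairs <- unique(samples$pair_id)
  purrr::map(pairs, function(p) run_pair_de(counts, samples, p, ...)) |>
    list_rbind()
}

#' Cross-pair recurrence and coordination summary
#'
#' For each feature, collects the pairs where it was called up and down, the
#' size of the larger consistent set, and whether the call was coordinated
#' (same direction in every pair).
#'
#' @param de A multi-pair DE tibble from [run_de()].
#' @return A tibble with `feature_id`, `pairs_up` and `pairs_down` (list
#'   columns), `n_pairs_consistent`, `coordinated`.
#' @export
summarize_recurrence <- function(de) {
  if (anyDuplicated(de[c("feature_id", "pair_id")]) > 0) {
    input_error("duplicate (feature_id, pair_id) rows in DE table")
  }
  n_pairs <- length(unique(de$pair_id))
  de |>
    group_by(.data$feature_id) |>
    summarise(
      pairs_up = list(sort(.data$pair_id[.data$direction == "up"])),
      pairs_down = list(sort(.data$pair_id[.data$direction == "down"])),
      .groups = "drop"
    ) |>
    mutate(
      n_up = map_int(.data$pairs_up, length),
      n_down = map_int(.data$pairs_down, length),
      n_pairs_consistent = pmax(.data$n_up, .data$n_down),
      coordinated = (.data$n_up == n_pairs & .data$n_down == 0) |
        (.data$n_down == n_pairs & .data$n_up == 0)
    ) |>
    select("feature_id", "pairs_up", "pairs_down", "n_pairs_consistent", "coordinated")
}

#' Venn cell counts of per-pair DE calls
#'
#' Counts, for each direction, the features whose set of calling pairs equals
#' each non-empty pair subset (exact Venn cells).
#'
#' @param de A multi-pair DE tibble from [run_de()].
#' @return A tibble with `direction`, `pair_set` (comma-joined), `n_features`.
#' @export
de_venn_counts <- function(de) {
  rec <- summarize_recurrence(de)
  cells <- function(sets, dirn) {
    keys <- map_chr(sets, paste, collapse = ",")
    keep <- keys != ""
    tibble(direction = dirn, pair_set = keys[keep]) |>
      count(.data$direction, .data$pair_set, name = "n_features")
  }
  bind_rows(cells(rec$pairs_up, "up"), cells(rec$pairs_down, "down")) |>
    arrange(.data$direction, .data$pair_set)
}

#' Volcano plot of one pair's DE results
#'
#' @param de A DE tibble (one or more pairs).
#' @return A ggplot object, faceted by pair.
#' @export
plot_de_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(.data$log2_fc, -log10(pmax(.data$fdr, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction), size = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    ggplot2::facet_wrap(~pair_id) +
    ggplot2::labs(x = "log2 fold change (tumor/normal)", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
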