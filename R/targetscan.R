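# Canonical miRNA target-site prediction on 3'UTRs: exact Watson-Crick seed
# matching (no wobble in the seed), a miRanda-style seed-weighted affine-gap
# local hybridization alignment on the package's own score scale, and an
# additive context-style site score. A gene passes for a miRNA when the
# summed alignment score clears a per-miRNA threshold (a fraction of that
# miRNA's perfect-duplex score) OR the best site context score is negative
# with at least a 7mer site.

SITE_LEN <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)
SITE_BASE_SCORE <- c("8mer" = -0.31, "7mer-m8" = -0.16, "7mer-A1" = -0.10, "6mer" = -0.03)

check_mirna_seq <- function(mirna_seq) {
  s <- normalize_rna(mirna_seq)
  if (any(nchar(s) < 16)) input_error("miRNA sequences shorter than 16 nt are not allowed")
  s
}

# Classify core-6mer match positions (1-based starts of the match to miRNA
# positions 2-7) into the canonical site grammar. `m8c` is the UTR base
# complementary to miRNA position 8 (the base 5' of the core match).
classify_sites <- function(utr, pos, m8c) {
  if (length(pos) == 0) {
    return(tibble(utr_start = integer(0), site_type = character(0)))
  }
  L <- nchar(utr)
  has_m8 <- pos >= 2 & str_sub(utr, pos - 1, pos - 1) == m8c
  has_a1 <- pos + 6 <= L & str_sub(utr, pos + 6, pos + 6) == "A"
  type <- dplyr::case_when(
    has_m8 & has_a1 ~ "8mer",
    has_m8 ~ "7mer-m8",
    has_a1 ~ "7mer-A1",
    TRUE ~ "6mer"
  )
  tibble(
    utr_start = as.integer(ifelse(has_m8, pos - 2L, pos - 1L)),
    site_type = type
  )
}

#' Find canonical seed-match sites of a miRNA on a 3'UTR
#'
#' Reports every position where the UTR (5' to 3') contains the exact
#' Watson-Crick reverse complement of miRNA positions 2-7, classified by the
#' canonical grammar: `6mer` (2-7 match), `7mer-m8` (2-8 match), `7mer-A1`
#' (2-7 match plus an A opposite miRNA position 1), `8mer` (both). Each
#' match is reported once with its maximal type; overlapping matches are all
#' reported (resolution happens in [call_targets()]). Coordinates are
#' 0-based offsets of the 5'-most site base.
#'
#' @param utr_seq UTR sequence (A/C/G/U; T accepted and mapped to U).
#' @param mirna_seq Mature miRNA sequence, 5' to 3', length >= 16.
#' @return A tibble with `utr_start` and `site_type` (scores unset).
#' @export
#' @examples
#' find_seed_sites("CCAAAACCUCAA", "UGAGGUUUUUUUUUUUUUUU")
find_seed_sites <- function(utr_seq, mirna_seq) {
  utr <- normalize_rna(utr_seq)
  m <- check_mirna_seq(mirna_seq)
  core7 <- rna_revcomp(str_sub(m, 2, 8))
  core6 <- str_sub(core7, 2, 7)
  hits <- Biostrings::matchPattern(core6, Biostrings::RNAString(utr))
  classify_sites(utr, Biostrings::start(hits), str_sub(core7, 1, 1)) |>
    arrange(.data$utr_start)
}

# 4x4 pair score lookup: Watson-Crick +5, G:U wobble +2, mismatch -4.
PAIR_SCORE <- local({
  P <- matrix(-4, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  P["A", "U"] <- P["U", "A"] <- P["C", "G"] <- P["G", "C"] <- 5
  P["G", "U"] <- P["U", "G"] <- 2
  P
})

#' Hybridization alignment score of a miRNA against a UTR window
#'
#' Best local alignment (affine gaps) of the reversed miRNA against the
#' window, read 5' to 3', scoring Watson-Crick pairs +5, G:U wobbles +2,
#' mismatches -4, gap open -8 (first gapped base included) and gap extension
#' -2, with all pair/mismatch terms doubled when the miRNA base lies in seed
#' positions 2-8. The score is dimensionless on the package's own scale; a
#' perfect 22-nt Watson-Crick duplex scores `5 * 15 + 10 * 7 = 145`.
#'
#' @param mirna_seq Mature miRNA sequence, 5' to 3', length >= 16.
#' @param utr_window UTR subsequence, at most 80 nt (callers slice windows).
#' @return Non-negative alignment score.
#' @export
hybrid_align_score <- function(mirna_seq, utr_window) {
  m <- check_mirna_seq(mirna_seq)
  if (nchar(utr_window) == 0) return(0)
  w <- normalize_rna(utr_window)
  if (nchar(w) > 80) input_error("UTR window longer than 80 nt; slice windows before aligning")
  mb <- rev(strsplit(m, "", fixed = TRUE)[[1]])
  wb <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(mb)
  L <- length(wb)
  # seed weighting refers to original miRNA positions 2-8
  seed_mult <- ifelse((n - seq_len(n) + 1) %in% 2:8, 2, 1)
  widx <- match(wb, RNA_BASES)
  best <- 0
  Hprev <- numeric(L + 1)
  Fcol <- rep(-Inf, L + 1)
  for (i in seq_len(n)) {
    sc <- PAIR_SCORE[mb[i], widx] * seed_mult[i]
    Hcur <- numeric(L + 1)
    E <- -Inf
    for (j in seq_len(L)) {
      E <- max(Hcur[j] - 8, E - 2)
      Fcol[j + 1] <- max(Hprev[j + 1] - 8, Fcol[j + 1] - 2)
      h <- max(0, Hprev[j] + sc[j], E, Fcol[j + 1])
      Hcur[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- Hcur
  }
  best
}

#' Perfect-duplex alignment score of a miRNA
#'
#' The [hybrid_align_score()] of the miRNA against its own reverse
#' complement; used to self-calibrate the per-miRNA alignment threshold.
#'
#' @param mirna_seq Mature miRNA sequence.
#' @return The perfect-duplex score (`5 * (len - 7) + 10 * 7` for a full
#'   Watson-Crick duplex).
#' @export
perfect_duplex_score <- function(mirna_seq) {
  m <- check_mirna_seq(mirna_seq)
  vapply(m, function(s) hybrid_align_score(s, rna_revcomp(s)), numeric(1), USE.NAMES = FALSE)
}

#' Context-style score of a target site
#'
#' Additive per-site repression score (more negative = stronger predicted
#' repression): a site-type base value (`8mer` -0.31, `7mer-m8` -0.16,
#' `7mer-A1` -0.10, `6mer` -0.03) minus `w_au` times the A/U fraction of the
#' 30-nt flanks on each side (truncated at UTR ends) minus `w_pos` times a
#' proximity term that is 1 for a site flush against a UTR end and 0 for a
#' centered site: `prox = max(0, 1 - 2 * min(d5, d3) / (L - len))` with
#' `d5`/`d3` the distances from the site to the UTR ends.
#'
#' @param utr_seq Full UTR sequence.
#' @param utr_start 0-based site start (vectorized).
#' @param site_type Site type string (vectorized).
#' @param w_au,w_pos Feature weights (defaults 0.1 each).
#' @return Numeric vector of context-style scores.
#' @export
context_like_score <- function(utr_seq, utr_start, site_type, w_au = 0.1, w_pos = 0.1) {
  utr <- normalize_rna(utr_seq)
  L <- nchar(utr)
  len <- SITE_LEN[site_type]
  if (any(is.na(len))) input_error("unknown site_type")
  if (any(utr_start < 0) || any(utr_start + len > L)) {
    input_error("site coordinates outside the UTR")
  }
  vapply(seq_along(utr_start), function(i) {
    s0 <- utr_start[i]
    sl <- len[i]
    left <- if (s0 > 0) str_sub(utr, max(1, s0 - 29), s0) else ""
    right <- if (s0 + sl < L) str_sub(utr, s0 + sl + 1, min(L, s0 + sl + 30)) else ""
    flank <- paste0(left, right)
    au <- if (nchar(flank) == 0) 0 else str_count(flank, "[AU]") / nchar(flank)
    d5 <- s0
    d3 <- L - (s0 + sl)
    prox <- if (L == sl) 1 else max(0, 1 - 2 * min(d5, d3) / (L - sl))
    unname(SITE_BASE_SCORE[site_type[i]]) - w_au * au - w_pos * prox
  }, numeric(1))
}

# Alignment window around a site: the miRNA 3' end pairs 5' of the seed
# match in the UTR, so the window extends upstream of the site.
site_window <- function(utr, utr_start, site_len, upstream = 30, downstream = 4) {
  L <- nchar(utr)
  from <- pmax(1, utr_start + 1 - upstream)
  to <- pmin(L, utr_start + site_len + downstream)
  str_sub(utr, from, to)
}

# Score a site table (utr_start, site_type) for one (gene, miRNA).
score_sites <- function(sites, utr, mirna_seq, w_au = 0.1, w_pos = 0.1) {
  if (nrow(sites) == 0) {
    sites$align_score <- numeric(0)
    sites$context_score <- numeric(0)
    return(sites)
  }
  len <- SITE_LEN[sites$site_type]
  wins <- site_window(utr, sites$utr_start, len)
  sites$align_score <- vapply(wins, function(w) hybrid_align_score(mirna_seq, w),
                              numeric(1), USE.NAMES = FALSE)
  sites$context_score <- context_like_score(utr, sites$utr_start, sites$site_type, w_au, w_pos)
  sites
}

#' Gene-level target call from scored sites
#'
#' Overlapping sites of the same (gene, miRNA) are resolved greedily by
#' descending alignment score (ties: leftmost). The call passes when the sum
#' of retained alignment scores reaches `align_min`, or when the minimum
#' retained context score is below `context_threshold` and at least one
#' retained site is a 7mer or better.
#'
#' @param sites Scored site tibble for a single (gene, miRNA): columns
#'   `gene_id`, `mirna_id`, `utr_start`, `site_type`, `align_score`,
#'   `context_score`. May have zero rows.
#' @param align_min Alignment pass threshold. Defaults to
#'   `align_min_frac * perfect_duplex_score(mirna_seq)` when `mirna_seq` is
#'   supplied.
#' @param mirna_seq Mature sequence used to self-calibrate `align_min`.
#' @param align_min_frac Fraction of the perfect-duplex score (default 0.9).
#' @param context_threshold Context pass threshold (default 0).
#' @param gene_id,mirna_id Ids used when `sites` has zero rows.
#' @return A one-row tibble: `gene_id`, `mirna_id`, `total_align_score`,
#'   `best_context_score`, `n_sites`, `passes`.
#' @export
call_targets <- function(sites, align_min = NULL, mirna_seq = NULL,
                         align_min_frac = 0.9, context_threshold = 0,
                         gene_id = NA_character_, mirna_id = NA_character_) {
  if (nrow(sites) > 0) {
    if (length(unique(sites$gene_id)) > 1 || length(unique(sites$mirna_id)) > 1) {
      input_error("call_targets() expects sites from a single (gene, miRNA)")
    }
    gene_id <- sites$gene_id[1]
    mirna_id <- sites$mirna_id[1]
  }
  if (is.null(align_min)) {
    if (is.null(mirna_seq)) input_error("supply either align_min or mirna_seq")
    align_min <- align_min_frac * perfect_duplex_score(mirna_seq)
  }
  if (nrow(sites) == 0) {
    return(tibble(
      gene_id = gene_id, mirna_id = mirna_id, total_align_score = 0,
      best_context_score = NA_real_, n_sites = 0L, passes = FALSE
    ))
  }
  ord <- order(-sites$align_score, sites$utr_start)
  len <- SITE_LEN[sites$site_type]
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(sites))
  for (i in ord) {
    s <- sites$utr_start[i]
    e <- s + len[i]
    if (all(e <= taken_start | s >= taken_end)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  ret <- sites[keep, ]
  has7 <- any(ret$site_type != "6mer")
  total <- sum(ret$align_score)
  bestc <- min(ret$context_score)
  tibble(
    gene_id = gene_id, mirna_id = mirna_id, total_align_score = total,
    best_context_score = bestc, n_sites = nrow(ret),
    passes = total >= align_min || (bestc < context_threshold && has7)
  )
}

#' Scan many genes against many miRNAs for scored target sites
#'
#' Runs the site grammar for every (miRNA, gene) combination (one vectorized
#' pattern match per miRNA across all UTRs) and scores each site with the
#' hybridization aligner and the context-style score.
#'
#' @param genes Gene tibble with `gene_id` and `utr_seq`.
#' @param mirnas miRNA tibble with `mirna_id` and `mature_seq`.
#' @param w_au,w_pos Context weights (defaults 0.1).
#' @return A scored site tibble: `gene_id`, `mirna_id`, `utr_start`,
#'   `site_type`, `align_score`, `context_score`.
#' @export
find_target_sites <- function(genes, mirnas, w_au = 0.1, w_pos = 0.1) {
  utrs <- normalize_rna(genes$utr_seq)
  subjects <- Biostrings::RNAStringSet(setNames(utrs, genes$gene_id))
  out <- vector("list", nrow(mirnas))
  for (k in seq_len(nrow(mirnas))) {
    m <- check_mirna_seq(mirnas$mature_seq[k])
    core7 <- rna_revcomp(str_sub(m, 2, 8))
    core6 <- str_sub(core7, 2, 7)
    m8c <- str_sub(core7, 1, 1)
    hits <- Biostrings::vmatchPattern(core6, subjects)
    starts <- Biostrings::startIndex(hits)
    rows <- list()
    for (g in which(lengths(starts) > 0)) {
      st <- classify_sites(utrs[g], starts[[g]], m8c)
      st <- score_sites(st, utrs[g], m, w_au, w_pos)
      st$gene_id <- genes$gene_id[g]
      rows[[length(rows) + 1]] <- st
    }
    if (length(rows) > 0) {
      tb <- bind_rows(rows)
      tb$mirna_id <- mirnas$mirna_id[k]
      out[[k]] <- tb
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(
      gene_id = character(0), mirna_id = character(0), utr_start = integer(0),
      site_type = character(0), align_score = numeric(0), context_score = numeric(0)
    ))
  }
  res |>
    select("gene_id", "mirna_id", "utr_start", "site_type", "align_score", "context_score") |>
    arrange(.data$mirna_id, .data$gene_id, .data$utr_start)
}

#' Gene-level target calls for a scored site table
#'
#' Applies [call_targets()] to every (gene, miRNA) group, self-calibrating
#' the alignment threshold per miRNA from its perfect-duplex score unless an
#' absolute `align_min` is given.
#'
#' @param sites Scored site tibble from [find_target_sites()].
#' @param mirnas miRNA tibble with `mirna_id` and `mature_seq`.
#' @param align_min Optional absolute threshold overriding self-calibration.
#' @param align_min_frac Fraction of the perfect-duplex score (default 0.9).
#' @param context_threshold Context pass threshold (default 0).
#' @return A tibble of target calls, one row per (gene, miRNA) with sites.
#' @export
call_targets_all <- function(sites, mirnas, align_min = NULL,
                             align_min_frac = 0.9, context_threshold = 0) {
  if (nrow(sites) == 0) {
    return(tibble(
      gene_id = character(0), mirna_id = character(0), total_align_score = numeric(0),
      best_context_score = numeric(0), n_sites = integer(0), passes = logical(0)
    ))
  }
  amin <- align_min
  thresholds <- setNames(
    if (is.null(amin)) align_min_frac * perfect_duplex_score(mirnas$mature_seq)
    else rep(amin, nrow(mirnas)),
    mirnas$mirna_id
  )
  sites |>
    group_by(.data$gene_id, .data$mirna_id) |>
    dplyr::group_map(function(g, key) {
      call_targets(
        mutate(g, gene_id = key$gene_id, mirna_id = key$mirna_id),
        align_min = thresholds[[key$mirna_id]],
        context_threshold = context_threshold
      )
    }) |>
    list_rbind() |>
    arrange(.data$mirna_id, .data$gene_id)
}

#' Write scored sites / target calls as TSV
#'
#' Scores are printed with 4 decimals.
#'
#' @param x A site or call tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) sprintf("%.4f", v))
  readr::write_tsv(x, path)
  invisible(path)
}
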