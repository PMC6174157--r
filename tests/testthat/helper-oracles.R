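# Independent oracles used across the suite. Each reimplements the quantity
# under test by a different route (direct density evaluation, substring
# scanning, exhaustive enumeration, plain dynamic programming) so that
# agreement is evidence, not tautology.

# --- conditional NB exact test: brute-force weight enumeration -------------
# w(i) = dnbinom(i; mu = s/2, size = 1/phi) * dnbinom(s - i; ...), two-sided
# p sums normalized weights w(i) <= w(obs) * (1 + 1e-9).
oracle_nb_p <- function(ya, s, phi) {
  if (s == 0) return(1)
  i <- 0:s
  w <- if (phi <= 0) {
    stats::dpois(i, s / 2) * stats::dpois(s - i, s / 2)
  } else {
    stats::dnbinom(i, size = 1 / phi, mu = s / 2) *
      stats::dnbinom(s - i, size = 1 / phi, mu = s / 2)
  }
  sum(w[w <= w[ya + 1] * (1 + 1e-9)]) / sum(w)
}

# exact two-tailed Binomial(s, 1/2) p-value with the same tie rule
oracle_binom_two_tail <- function(ya, s) {
  if (s == 0) return(1)
  w <- stats::dbinom(0:s, s, 0.5)
  sum(w[w <= w[ya + 1] * (1 + 1e-9)])
}

# --- Benjamini-Hochberg step-up by hand ------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in seq(m, 1)) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  adj
}

# --- canonical seed-site grammar: naive substring scan ---------------------
# Enumerates every UTR offset, compares 6-mers by substring equality and
# classifies m8/A1 extensions by direct character checks.
oracle_seed_scan <- function(utr, mirna) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mb <- strsplit(mirna, "")[[1]]
  core6 <- paste(rev(comp[mb[2:7]]), collapse = "")
  m8c <- comp[[mb[8]]]
  L <- nchar(utr)
  if (L < 6) {
    return(data.frame(utr_start = integer(0), site_type = character(0)))
  }
  starts <- integer(0)
  types <- character(0)
  for (p in 1:(L - 5)) {
    if (substring(utr, p, p + 5) != core6) next
    has_m8 <- p >= 2 && substring(utr, p - 1, p - 1) == m8c
    has_a1 <- p + 6 <= L && substring(utr, p + 6, p + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    starts <- c(starts, if (has_m8) p - 2L else p - 1L)
    types <- c(types, type)
  }
  data.frame(utr_start = starts, site_type = types)
}

# --- hybridization alignment: plain O(n^3) local DP ------------------------
# Same scoring semantics (WC +5, G:U +2, mismatch -4, seed positions 2-8
# doubled for pair/mismatch, gap of length k costs 8 + 2*(k-1)), written as
# an explicit best-over-all-gap-lengths recursion with full matrices.
oracle_align <- function(mirna, window) {
  if (nchar(window) == 0) return(0)
  pair_sc <- function(a, b) {
    wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")
    gu <- (a == "G" && b == "U") || (a == "U" && b == "G")
    if (wc) 5 else if (gu) 2 else -4
  }
  mb <- rev(strsplit(mirna, "")[[1]])
  wb <- strsplit(window, "")[[1]]
  n <- length(mb)
  L <- length(wb)
  seed <- (n - seq_len(n) + 1) %in% 2:8
  H <- matrix(0, n + 1, L + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:L) {
      sc <- pair_sc(mb[i], wb[j]) * (if (seed[i]) 2 else 1)
      cand <- c(0, H[i, j] + sc)
      for (k in 1:j) cand <- c(cand, H[i + 1, j + 1 - k] - 8 - 2 * (k - 1))
      for (k in 1:i) cand <- c(cand, H[i + 1 - k, j + 1] - 8 - 2 * (k - 1))
      H[i + 1, j + 1] <- max(cand)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# --- hypergeometric upper tail ---------------------------------------------
# direct combinatorial sum
oracle_hyper_sum <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# run hypergeom_enrich for a single constructed (N, K, n, k) instance and
# return its p-value
enrich_p <- function(k, K, n, N, fun = hypergeom_enrich, ...) {
  universe <- sprintf("g%02d", seq_len(N))
  term <- list(T1 = universe[seq_len(K)])
  study <- c(universe[seq_len(k)], universe[(K + 1):N][seq_len(n - k)])
  stopifnot(length(study) == n)
  fun(study, universe, term, ...)$p_value
}

# --- shared fixtures --------------------------------------------------------
small_sim_config <- function(seed = 1, ...) {
  simulation_config(
    n_genes = 200, n_tfs = 30, n_mirnas = 40, planted_up_mirnas = 10,
    planted_down_mirnas = 2, hub_site_mirnas = 6, n_target_genes = 12,
    mirnas_per_target = c(3, 6), rng_seed = seed, ...
  )
}

random_rna_str <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# random miRNA whose seed region is well-defined
random_mirna_str <- function() random_rna_str(sample(19:23, 1))
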