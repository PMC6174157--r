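# Classed error helpers so callers can distinguish configuration problems
# from malformed inputs and generation failures.
cfg_error <- function(msg) abort(msg, class = "mircoop_config_error")
input_error <- function(msg) abort(msg, class = "mircoop_input_error")
gen_error <- function(msg) abort(msg, class = "mircoop_generation_error")
io_error <- function(msg) abort(msg, class = "mircoop_io_error")

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases the sequence and maps T to U. Any character outside
#' \{A, C, G, U\} after normalization is an error naming the offending
#' position.
#'
#' @param x Character vector of sequences.
#' @return Character vector over \{A, C, G, U\}.
#' @export
#' @examples
#' normalize_rna("acgt")
normalize_rna <- function(x) {
  out <- chartr("Tt", "Uu", toupper(x))
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    input_error(sprintf(
      "non-nucleotide character '%s' at position %d of sequence %d",
      substr(out[i], bad[i], bad[i]), bad[i], i
    ))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of RNA sequences (A/C/G/U).
#' @return Character vector of reverse complements, 5' to 3'.
#' @export
#' @examples
#' rna_revcomp("AUGC")
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

# Random RNA strings of the given lengths (vectorized over `lengths`).
random_rna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(RNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Stable per-stage seed derivation: one user seed drives every stochastic
# stage through a fixed documented offset, keeping each stage individually
# reproducible. Offsets stay small so seed + offset < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    transcriptome = 101L, mirnome = 202L, plant = 303L, counts = 404L,
    wallenius_mc = 505L
  )
  if (!stage %in% names(offsets)) abort(paste("unknown stage", stage))
  as.integer(seed) + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
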