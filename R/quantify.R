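# Within-sample quantification: RPKM for mRNA (per-kilobase, per million
# uniquely mapped reads), TPM for miRNA (per million total clean reads) and
# CPM (per million of the column sum), plus the expression filters built on
# them. No between-sample normalization factors are applied.

# Split a counts tibble into ids / lengths / numeric sample matrix.
count_parts <- function(counts) {
  if (!is.data.frame(counts) || !"feature_id" %in% names(counts)) {
    input_error("counts must be a data frame with a 'feature_id' column")
  }
  scols <- setdiff(names(counts), c("feature_id", "length"))
  if (length(scols) == 0) input_error("counts has no sample columns")
  mat <- as.matrix(counts[scols])
  storage.mode(mat) <- "double"
  rownames(mat) <- counts$feature_id
  if (any(is.na(mat)) || any(mat < 0)) input_error("counts must be non-negative and complete")
  list(
    feature_ids = counts$feature_id,
    lengths = if ("length" %in% names(counts)) counts$length else NULL,
    mat = mat
  )
}

norm_tbl <- function(parts, mat, unit) {
  out <- tibble(feature_id = parts$feature_ids)
  for (j in colnames(mat)) out[[j]] <- unname(mat[, j])
  attr(out, "unit") <- unit
  out
}

#' Units of a normalized matrix
#'
#' @param x A normalized tibble from [compute_rpkm()], [compute_tpm_mirna()]
#'   or [compute_cpm()].
#' @return The unit string (`"RPKM"`, `"TPM"` or `"CPM"`).
#' @export
norm_unit <- function(x) attr(x, "unit")

#' RPKM normalization
#'
#' Reads per kilobase of exonic length per million uniquely mapped reads:
#' `count / (length_kb * uniquely_mapped_reads / 1e6)`. Lengths come from the
#' `length` column of `counts`; the per-million denominator uses
#' `uniquely_mapped_reads` from `samples` (only unambiguously aligned reads
#' enter the RPKM calculation).
#'
#' @param counts Count tibble (`feature_id`, `length`, sample columns).
#' @param samples Sample metadata with `sample_id` and `uniquely_mapped_reads`.
#' @return A tibble of RPKM values with unit attribute `"RPKM"`.
#' @export
#' @examples
#' counts <- tibble::tibble(feature_id = "g1", length = 2000L, s1 = 100L)
#' samples <- tibble::tibble(sample_id = "s1", uniquely_mapped_reads = 1e7)
#' compute_rpkm(counts, samples)  # 5 RPKM
compute_rpkm <- function(counts, samples) {
  parts <- count_parts(counts)
  if (is.null(parts$lengths)) {
    input_error(paste(
      "feature lengths missing for RPKM; no 'length' column for features:",
      paste(head(parts$feature_ids, 5), collapse = ", ")
    ))
  }
  if (any(is.na(parts$lengths) | parts$lengths <= 0)) {
    bad <- parts$feature_ids[which(is.na(parts$lengths) | parts$lengths <= 0)]
    input_error(paste("non-positive feature lengths for:", paste(head(bad, 5), collapse = ", ")))
  }
  mapped <- samples$uniquely_mapped_reads[match(colnames(parts$mat), samples$sample_id)]
  if (any(is.na(mapped) | mapped <= 0)) {
    bad <- colnames(parts$mat)[which(is.na(mapped) | mapped <= 0)]
    input_error(paste("zero or missing uniquely mapped reads for sample:", paste(bad, collapse = ", ")))
  }
  denom <- outer(parts$lengths / 1e3, mapped / 1e6)
  norm_tbl(parts, parts$mat / denom, "RPKM")
}

#' miRNA TPM normalization
#'
#' Tags per million total clean reads: `count / total_clean_reads * 1e6`.
#' The denominator is the sample's total clean read count (not the column
#' sum), so column sums are at most 1e6, with equality exactly when every
#' clean read was counted to a feature.
#'
#' @param counts Count tibble (`feature_id`, sample columns).
#' @param samples Sample metadata with `sample_id` and `total_clean_reads`.
#' @return A tibble of TPM values with unit attribute `"TPM"`.
#' @export
compute_tpm_mirna <- function(counts, samples) {
  parts <- count_parts(counts)
  totals <- samples$total_clean_reads[match(colnames(parts$mat), samples$sample_id)]
  if (any(is.na(totals) | totals <= 0)) {
    bad <- colnames(parts$mat)[which(is.na(totals) | totals <= 0)]
    input_error(paste("zero or missing total clean reads for sample:", paste(bad, collapse = ", ")))
  }
  if (any(colSums(parts$mat) > totals)) {
    bad <- colnames(parts$mat)[colSums(parts$mat) > totals]
    input_error(paste("column sum exceeds total clean reads for sample:", paste(bad, collapse = ", ")))
  }
  norm_tbl(parts, sweep(parts$mat, 2, totals / 1e6, "/"), "TPM")
}

#' CPM normalization
#'
#' Counts per million of the column sum: `count / colsum * 1e6`; each column
#' sums to exactly 1e6.
#'
#' @param counts Count tibble (`feature_id`, sample columns).
#' @return A tibble of CPM values with unit attribute `"CPM"`.
#' @export
compute_cpm <- function(counts) {
  parts <- count_parts(counts)
  if (nrow(parts$mat) == 0) input_error("empty count matrix")
  cs <- colSums(parts$mat)
  if (any(cs <= 0)) {
    input_error(paste("zero column sum for sample:", paste(colnames(parts$mat)[cs <= 0], collapse = ", ")))
  }
  norm_tbl(parts, sweep(parts$mat, 2, cs / 1e6, "/"), "CPM")
}

#' Expression filter on a normalized matrix
#'
#' Returns the features whose value meets the threshold in at least
#' `min_samples` samples. The comparison is `>=` for the RPKM-style rule
#' ("RPKM >= 1 in any sample") and `>` for the CPM/TPM-style rule ("above 1
#' in at least 1 sample"); both are selectable.
#'
#' @param values Normalized tibble (`feature_id` + sample columns).
#' @param threshold Expression threshold (default 1).
#' @param min_samples Minimum number of samples meeting it (default 1).
#' @param comparison `">="` or `">"` (default `">="`).
#' @return Character vector of retained feature ids.
#' @export
filter_expressed <- function(values, threshold = 1, min_samples = 1,
                             comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  if (min_samples < 1) input_error("min_samples must be >= 1")
  parts <- count_parts(values)
  hit <- if (comparison == ">=") parts$mat >= threshold else parts$mat > threshold
  parts$feature_ids[rowSums(hit) >= min_samples]
}

#' Write/read a normalized matrix TSV with a unit header comment
#'
#' The first line is `#unit=RPKM|TPM|CPM`; the rest is a plain TSV.
#'
#' @param values Normalized tibble with a unit attribute.
#' @param path File path.
#' @return `read_norm_tsv()` returns the tibble with its unit attribute
#'   restored; `write_norm_tsv()` the path.
#' @export
write_norm_tsv <- function(values, path) {
  writeLines(sprintf("#unit=%s", norm_unit(values) %||% "NA"), path)
  readr::write_tsv(values, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_norm_tsv
#' @export
read_norm_tsv <- function(path) {
  unit <- sub("^#unit=", "", readLines(path, n = 1))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(out, "unit") <- unit
  out
}
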