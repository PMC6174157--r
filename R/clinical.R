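# Closed-form clinical and bench formulas: immunohistochemistry histoscore
# with high/low classification, 2^-delta-delta-Ct relative expression, and
# xenograft tumor volume.

#' Histoscore of one IHC field
#'
#' Nuclear positive ratio times staining intensity (0 none, 1 mild, 2
#' moderate, 3 intense); bounded by \[0, 3\].
#'
#' @param positive_ratio Fraction of positive nuclei in \[0, 1\] (vectorized).
#' @param intensity Integer staining intensity in \{0, 1, 2, 3\} (vectorized).
#' @return Numeric field scores.
#' @export
#' @examples
#' field_histoscore(0.5, 2)  # 1.0
field_histoscore <- function(positive_ratio, intensity) {
  if (any(positive_ratio < 0 | positive_ratio > 1, na.rm = FALSE) ||
      any(is.na(positive_ratio))) {
    input_error("positive_ratio must lie in [0, 1]")
  }
  if (any(!intensity %in% 0:3)) input_error("intensity must be one of 0, 1, 2, 3")
  positive_ratio * intensity
}

#' Total histoscore over exactly four fields
#'
#' Sum of the four per-field scores; bounded by \[0, 12\].
#'
#' @param positive_ratios Numeric vector of exactly 4 positive ratios.
#' @param intensities Integer vector of exactly 4 intensities.
#' @return The total staining score.
#' @export
#' @examples
#' total_histoscore(c(0.5, 0.3, 0, 0.9), c(2, 1, 0, 3))  # 4.0
total_histoscore <- function(positive_ratios, intensities) {
  if (length(positive_ratios) != 4 || length(intensities) != 4) {
    input_error("total_histoscore() requires exactly 4 fields")
  }
  sum(field_histoscore(positive_ratios, intensities))
}

#' High/low expression classification of a staining score
#'
#' `"high"` when the score reaches the cutoff (boundary inclusive), `"low"`
#' otherwise. The default cutoff 1.07 is the published operating point for
#' nuclear ROR-alpha staining and is shipped as a constant, not recomputed.
#'
#' @param score Non-negative staining score (vectorized).
#' @param cutoff Classification cutoff (default 1.07).
#' @return Character vector `"high"`/`"low"`.
#' @export
#' @examples
#' classify_expression(c(1.07, 1.0699))  # "high" "low"
classify_expression <- function(score, cutoff = 1.07) {
  if (any(score < 0)) input_error("score must be >= 0")
  ifelse(score >= cutoff, "high", "low")
}

#' Relative expression by the 2^-delta(delta-Ct) method
#'
#' `delta Ct = Ct(target) - Ct(reference)` (reference: actin for mRNA, U6 for
#' miRNA). Without a calibrator the result is `2^-deltaCt`; with one it is
#' `2^-(deltaCt_sample - deltaCt_calibrator)`.
#'
#' @param ct_target,ct_reference Cycle-threshold values of the sample
#'   (positive, finite).
#' @param calibrator Optional list/vector with `ct_target` and `ct_reference`
#'   of the calibrator.
#' @return Positive relative expression.
#' @export
#' @examples
#' relative_expression(25, 20, calibrator = c(ct_target = 24, ct_reference = 20))
relative_expression <- function(ct_target, ct_reference, calibrator = NULL) {
  chk <- function(x) all(is.finite(x)) && all(x > 0)
  if (!chk(ct_target) || !chk(ct_reference)) {
    input_error("Ct values must be positive and finite")
  }
  dct <- ct_target - ct_reference
  if (!is.null(calibrator)) {
    cal <- as.list(calibrator)
    if (!chk(cal$ct_target) || !chk(cal$ct_reference)) {
      input_error("calibrator Ct values must be positive and finite")
    }
    dct <- dct - (cal$ct_target - cal$ct_reference)
  }
  2^(-dct)
}

#' Xenograft tumor volume
#'
#' `volume = length * width^2 / 2`, with length the biggest and width the
#' smallest diameter (mm); the result is in mm^3.
#'
#' @param length Largest tumor diameter in mm (vectorized).
#' @param width Smallest tumor diameter in mm (vectorized).
#' @return Tumor volumes in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(length, width) {
  if (any(width <= 0)) input_error("width must be positive")
  if (any(width > length)) {
    input_error("width exceeds length; length must be the biggest diameter")
  }
  length * width^2 / 2
}

#' Batch IHC scoring
#'
#' Scores a table of spots with four (ratio, intensity) field pairs per row,
#' returning the total histoscore and the high/low class.
#'
#' @param spots Data frame with columns `ratio_1..ratio_4` and
#'   `intensity_1..intensity_4` (an id column is carried through).
#' @param cutoff High/low cutoff (default 1.07).
#' @return The input tibble plus `total_score` and `class` columns.
#' @export
score_ihc <- function(spots, cutoff = 1.07) {
  need <- c(paste0("ratio_", 1:4), paste0("intensity_", 1:4))
  missing_cols <- setdiff(need, names(spots))
  if (length(missing_cols) > 0) {
    input_error(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  fields <- vapply(1:4, function(i) {
    field_histoscore(spots[[paste0("ratio_", i)]], spots[[paste0("intensity_", i)]])
  }, numeric(nrow(spots)))
  total <- rowSums(matrix(fields, nrow = nrow(spots)))
  as_tibble(spots) |>
    mutate(total_score = total, class = classify_expression(total, cutoff))
}
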