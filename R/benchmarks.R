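#' Landis-Koch verbal benchmark for agreement coefficients
#'
#' Maps a chance-corrected agreement coefficient to the conventional
#' verbal bands: "Poor" (< 0.0), "Slight" (0.0-0.20), "Fair" (0.21-0.40),
#' "Moderate" (0.41-0.60), "Substantial" (0.61-0.80) and "Almost perfect"
#' (0.81-1.00). Band edges are resolved on the coefficient rounded to two
#' decimals, so the printed bands partition with no gaps.
#'
#' @param coefficient Numeric vector of agreement coefficients (at most 1).
#' @return Character vector of benchmark labels (`NA` in, `NA` out).
#' @examples
#' landis_koch(c(0.919, 0.630, -0.1))
#' @export
landis_koch <- function(coefficient) {
  r <- round_half_up(coefficient, 2)
  if (any(r > 1 + 1e-9, na.rm = TRUE)) {
    abort("agreement coefficients cannot exceed 1")
  }
  labels <- c("Poor", "Slight", "Fair", "Moderate", "Substantial",
              "Almost perfect")
  idx <- findInterval(r, c(0, 0.21, 0.41, 0.61, 0.81) - 1e-9) + 1L
  out <- labels[idx]
  out[is.na(r)] <- NA_character_
  out
}

#' Hinkle rule-of-thumb interpretation of a correlation coefficient
#'
#' Verbal bands for the magnitude of a Pearson correlation: "negligible"
#' (|r| up to 0.30), "low" (to 0.50), "moderate" (to 0.70), "high" (to
#' 0.90) and "very high" (0.90 to 1.00), with the direction ("positive"/
#' "negative") reported alongside for non-negligible correlations. Edges
#' are resolved on the two-decimal |r|; 0.90 itself reads "very high", the
#' lower bound of its printed band.
#'
#' @param r Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return Character vector such as `"very high positive correlation"`.
#' @examples
#' hinkle_interpretation(c(0.909, -0.95, 0.2))
#' @export
hinkle_interpretation <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) {
    abort("correlation coefficients must lie in [-1, 1]")
  }
  a <- round_half_up(abs(r), 2)
  size <- c("negligible", "low", "moderate", "high", "very high")[
    findInterval(a, c(0.305, 0.505, 0.705, 0.895)) + 1L
  ]
  direction <- ifelse(r >= 0, "positive", "negative")
  out <- ifelse(size == "negligible",
                "negligible correlation",
                paste(size, direction, "correlation"))
  out[is.na(r)] <- NA_character_
  out
}
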