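.rih_default_config <- function() {
  list(
    grade_points = c(A = 5, B = 4, C = 2, D = 1),
    source_points = c(`1` = 1, `2` = 2, `3` = 3),
    availability_threshold = 7,
    n_attributes = 9,
    quality_threshold = 2,
    interval_upper = c(2.0, 3.0, 4.0, 5.0),
    interval_labels = c(
      "Almost no RIH features are present",
      "Few RIH features are present",
      "Many RIH features are present",
      "Almost all RIH features are present"
    ),
    score_digits = 1,
    conf_level = 0.95
  )
}

#' Assessment configuration
#'
#' All constants of the RIH instrument live in one configuration object:
#' the non-equidistant grade-to-point map (A = 5, B = 4, C = 2, D = 1), the
#' source-quality points (type 1/2/3 worth 1/2/3 points), the availability
#' threshold (at least 7 of the 9 attributes documented), the source-quality
#' threshold (mean source points of at least 2), and the four overall-score
#' intervals with their verbal labels. Defaults reproduce the published
#' instrument; any override is flagged `canonical = FALSE` and downstream
#' print methods mark results as non-canonical.
#'
#' @param grade_points Named numeric vector mapping grades A-D to points.
#' @param source_points Named numeric vector mapping source types to points.
#' @param availability_threshold Minimum documented attributes for the
#'   overall score to be meaningful.
#' @param n_attributes Number of assessment attributes (9).
#' @param quality_threshold Minimum mean source-quality points.
#' @param interval_upper Upper edges (inclusive, on the rounded score) of
#'   the four classification intervals, in increasing order.
#' @param interval_labels Verbal labels for the intervals, lowest first.
#' @param score_digits Decimal places kept for the overall score and the
#'   quality mean (half-up rounding).
#' @param conf_level Confidence level used by agreement and correlation
#'   estimates.
#' @return A list of class `rih_config`.
#' @examples
#' rih_config()$grade_points
#' @export
rih_config <- function(grade_points = c(A = 5, B = 4, C = 2, D = 1),
                       source_points = c(`1` = 1, `2` = 2, `3` = 3),
                       availability_threshold = 7,
                       n_attributes = 9,
                       quality_threshold = 2,
                       interval_upper = c(2.0, 3.0, 4.0, 5.0),
                       interval_labels = c(
                         "Almost no RIH features are present",
                         "Few RIH features are present",
                         "Many RIH features are present",
                         "Almost all RIH features are present"
                       ),
                       score_digits = 1,
                       conf_level = 0.95) {
  cfg <- list(
    grade_points = grade_points,
    source_points = source_points,
    availability_threshold = availability_threshold,
    n_attributes = n_attributes,
    quality_threshold = quality_threshold,
    interval_upper = interval_upper,
    interval_labels = interval_labels,
    score_digits = score_digits,
    conf_level = conf_level
  )
  if (is.null(names(cfg$grade_points)) || anyNA(cfg$grade_points)) {
    abort("`grade_points` must be a complete named numeric vector.")
  }
  if (length(cfg$interval_upper) != length(cfg$interval_labels)) {
    abort("`interval_upper` and `interval_labels` must have equal length.")
  }
  if (is.unsorted(cfg$interval_upper, strictly = TRUE)) {
    abort("`interval_upper` must be strictly increasing.")
  }
  if (cfg$conf_level <= 0 || cfg$conf_level >= 1) {
    abort("`conf_level` must lie strictly between 0 and 1.")
  }
  cfg$canonical <- identical(cfg, .rih_default_config())
  structure(cfg, class = "rih_config")
}

#' @export
print.rih_config <- function(x, ...) {
  cat("<rih_config>", if (x$canonical) "(canonical)" else "(NON-CANONICAL)", "\n")
  cat("  grade points:     ",
      paste(names(x$grade_points), x$grade_points, sep = "=", collapse = " "), "\n")
  cat("  source points:    ",
      paste(names(x$source_points), x$source_points, sep = "=", collapse = " "), "\n")
  cat("  availability:     >=", x$availability_threshold, "of",
      x$n_attributes, "attributes\n")
  cat("  quality:          mean source points >=", x$quality_threshold, "\n")
  cat("  intervals:        ",
      paste(sprintf("(..%.1f] %s", x$interval_upper, x$interval_labels),
            collapse = "; "), "\n")
  invisible(x)
}
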