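#' Overall responsibility score from attribute points
#'
#' The overall score is the plain arithmetic mean of the grade points over
#' the documented attributes only (missing grades are skipped, not imputed),
#' reported half-up to one decimal. All attributes carry equal weight.
#'
#' @param points Numeric vector of attribute points; `NA` marks an
#'   undocumented attribute.
#' @param config An [rih_config()] object.
#' @return The rounded mean score, a single number in `[1, 5]`.
#' @examples
#' overall_score(c(4, 4, 5, 4, 5, 5, 5, 4, 5)) # 4.6
#' overall_score(c(5, 1, NA, 2, 4, 1, NA, 1, 2)) # 16/7 -> 2.3
#' @export
overall_score <- function(points, config = rih_config()) {
  pts <- points[!is.na(points)]
  if (length(pts) == 0) {
    abort("no score: zero documented attributes", class = "rih_no_score")
  }
  round_half_up(mean(pts), config$score_digits)
}

#' Classify an overall score into the four-interval verbal scale
#'
#' Scores, already rounded to one decimal, fall into exactly one of four
#' intervals: 1.0-2.0 "Almost no RIH features are present", 2.1-3.0 "Few",
#' 3.1-4.0 "Many", 4.1-5.0 "Almost all". Because classification operates on
#' the rounded score, the printed interval edges partition with no gaps
#' (a raw 2.05 rounds to 2.1 and reads "Few").
#'
#' @param score Numeric vector of overall scores in `[1, 5]`; values are
#'   rounded to the configured number of decimals before classification.
#'   `NA` passes through.
#' @param config An [rih_config()] object.
#' @return Character vector of interval labels.
#' @examples
#' classify_interval(c(4.6, 3.6, 2.3, 1.0))
#' @export
classify_interval <- function(score, config = rih_config()) {
  r <- round_half_up(score, config$score_digits)
  out_of_range <- !is.na(r) & (r < 1 - 1e-9 | r > max(config$interval_upper) + 1e-9)
  if (any(out_of_range)) {
    abort(paste0("score out of range [1, ", max(config$interval_upper),
                 "]: ", paste(r[out_of_range], collapse = ", ")))
  }
  idx <- findInterval(r, config$interval_upper + 1e-9) + 1L
  out <- config$interval_labels[idx]
  out[is.na(r)] <- NA_character_
  out
}

#' Rating step: per-innovation scorecard summaries
#'
#' The rating step condenses each scorecard into two components plus the
#' overall score:
#'
#' * **availability**: `n_documented`, the number of attributes with a
#'   grade, and whether it reaches the threshold (>= 7 of 9);
#' * **quality**: `quality_mean`, the mean of best-source points over
#'   attributes that have both a grade and a recorded source, and whether it
#'   reaches the threshold (>= 2);
#' * **overall_score** with its interval label.
#'
#' An overall score is `meaningful` only when both the availability and the
#' quality components clear their thresholds. The rating is computed even
#' for innovations that fail screening (the screening outcome is reported
#' alongside so the two judgments stay distinct). An attribute graded
#' without any recorded source still counts toward availability but is
#' excluded from the quality mean, with a warning.
#'
#' @param scorecards Long scorecard tibble (see [scorecard()]); screening
#'   rows are optional, attribute rows are required.
#' @param config An [rih_config()] object.
#' @return A tibble of class `rih_ratings`, one row per innovation:
#'   `innovation_id`, `region`, `proceed` (screening outcome, `NA` if no
#'   screening rows), `n_documented`, `availability_sufficient`,
#'   `quality_mean`, `quality_sufficient`, `overall_score`, `interval`,
#'   `meaningful`. Per-attribute detail (grade, points, best source) is
#'   attached as `attr(, "details")`.
#' @examples
#' sc <- scorecard("demo", points_to_grade(c(4, 4, 5, 4, 5, 5, 5, 4, 5)),
#'                 sources = rep(3, 9))
#' rih_rate(sc)
#' @export
rih_rate <- function(scorecards, config = rih_config()) {
  scorecards <- validate_scorecards(scorecards)
  attrs <- .attribute_ids()

  details <- scorecards |>
    dplyr::filter(.data$criterion_or_attribute %in% attrs) |>
    dplyr::transmute(
      innovation_id = .data$innovation_id,
      region = .data$region,
      attribute = .data$criterion_or_attribute,
      grade = .data$value,
      points = grade_points_na(.data$value, config),
      best_source = .data$source_type,
      source_pts = source_points(.data$source_type, config)
    )
  if (nrow(details) == 0) {
    abort("no attribute rows to rate")
  }
  incomplete <- details |>
    dplyr::count(.data$innovation_id) |>
    dplyr::filter(.data$n != config$n_attributes)
  if (nrow(incomplete) > 0) {
    abort(paste0("scorecards must carry all ", config$n_attributes,
                 " attributes; incomplete: ",
                 paste(incomplete$innovation_id, collapse = ", ")))
  }

  graded_unsourced <- !is.na(details$points) & is.na(details$best_source)
  if (any(graded_unsourced)) {
    warn(paste0(
      sum(graded_unsourced),
      " graded attribute(s) without a recorded source count toward",
      " availability but are excluded from the quality mean"
    ))
  }

  out <- details |>
    dplyr::group_by(.data$innovation_id, .data$region) |>
    dplyr::summarise(
      n_documented = sum(!is.na(.data$points)),
      quality_mean = {
        q <- .data$source_pts[!is.na(.data$points) & !is.na(.data$source_pts)]
        if (length(q) == 0) NA_real_
        else round_half_up(mean(q), config$score_digits)
      },
      overall_score = if (all(is.na(.data$points))) NA_real_
                      else round_half_up(mean(.data$points, na.rm = TRUE),
                                         config$score_digits),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      availability_sufficient = .data$n_documented >= config$availability_threshold,
      quality_sufficient = .data$quality_mean >= config$quality_threshold,
      interval = classify_interval(.data$overall_score, config),
      meaningful = .data$availability_sufficient & .data$quality_sufficient
    ) |>
    dplyr::select(
      "innovation_id", "region", "n_documented", "availability_sufficient",
      "quality_mean", "quality_sufficient", "overall_score", "interval",
      "meaningful"
    )

  if (any(out$n_documented == 0)) {
    warn(paste0("no score (zero documented attributes) for: ",
                paste(out$innovation_id[out$n_documented == 0],
                      collapse = ", ")))
  }
  no_quality <- is.na(out$quality_mean) & out$n_documented > 0
  if (any(no_quality)) {
    warn(paste0("quality not assessable (no sourced attribute) for: ",
                paste(out$innovation_id[no_quality], collapse = ", ")))
  }

  screening_present <- any(scorecards$criterion_or_attribute %in% .criterion_ids())
  if (screening_present) {
    scr <- rih_screen(scorecards)
    out <- dplyr::left_join(out,
                            dplyr::select(scr, "innovation_id", "proceed"),
                            by = "innovation_id")
  } else {
    out$proceed <- NA
  }
  out <- dplyr::relocate(out, "proceed", .after = "region")

  structure(out,
            class = c("rih_ratings", class(out)),
            details = details,
            canonical = config$canonical)
}

#' @export
print.rih_ratings <- function(x, ...) {
  if (isFALSE(attr(x, "canonical"))) {
    cat("Note: rated under a NON-CANONICAL configuration\n")
  }
  NextMethod()
}
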