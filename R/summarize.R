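#' Sample-level summary of scorecards
#'
#' Reproduces the standard reporting layout for a sample of assessed
#' innovations: screening include/exclude counts with percentages, the
#' per-attribute grade distribution (counts and percent of documented
#' attributes), per-attribute point statistics (mean, SD, min, max over
#' documented attributes), and the rating-step distributions (availability,
#' source quality, overall-score interval), plus overall-score statistics.
#'
#' @param scorecards Long scorecard tibble for one or more innovations.
#' @param config An [rih_config()] object.
#' @return An object of class `rih_summary`: a list of tibbles
#'   `$screening`, `$grades`, `$points`, `$rating`, `$overall`, with the
#'   sample size in `$n`. Percentages are half-up integer percents;
#'   `$grades$cell` carries the conventional `"21 (84%)"` formatting.
#' @examples
#' sc <- dplyr::bind_rows(
#'   scorecard("a", rep("A", 9), sources = rep(3, 9)),
#'   scorecard("b", rep(c("A", "C", "C"), 3), sources = rep(2, 9))
#' )
#' rih_summarize(sc)
#' @export
rih_summarize <- function(scorecards, config = rih_config()) {
  scorecards <- validate_scorecards(scorecards)
  if (nrow(scorecards) == 0) abort("cannot summarize an empty sample")

  ratings <- suppressWarnings(rih_rate(scorecards, config))
  details <- attr(ratings, "details")
  n <- nrow(ratings)
  crits <- rih_screening_criteria()

  # screening: include/exclude per criterion, then the overall outcome
  screening <- NULL
  if (any(scorecards$criterion_or_attribute %in% crits$criterion)) {
    scr <- rih_screen(scorecards)
    per_crit <- purrr::map2_dfr(crits$criterion, crits$include_answer,
      function(cr, inc) {
        n_inc <- sum(scr[[cr]] == inc)
        tibble(criterion = cr, n_include = n_inc, n_exclude = n - n_inc)
      })
    outcome <- tibble(criterion = "screening_outcome",
                      n_include = sum(scr$proceed),
                      n_exclude = sum(!scr$proceed))
    screening <- dplyr::bind_rows(per_crit, outcome) |>
      dplyr::mutate(pct_include = pct_of(.data$n_include, n),
                    pct_exclude = pct_of(.data$n_exclude, n))
  }

  # grade distribution: % of documented attributes, as counts and cells
  grades <- details |>
    dplyr::filter(!is.na(.data$grade)) |>
    dplyr::count(.data$attribute, .data$grade) |>
    tidyr::complete(attribute = .attribute_ids(),
                    grade = names(config$grade_points),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$attribute) |>
    dplyr::mutate(n_documented = sum(.data$n),
                  pct = pct_of(.data$n, .data$n_documented),
                  cell = format_count_pct(.data$n, .data$pct)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$attribute, .attribute_ids()),
                   match(.data$grade, names(config$grade_points)))

  points <- details |>
    dplyr::group_by(.data$attribute) |>
    dplyr::summarise(
      n_documented = sum(!is.na(.data$points)),
      mean = round_half_up(mean(.data$points, na.rm = TRUE), 1),
      sd = round_half_up(sd(.data$points, na.rm = TRUE), 1),
      min = suppressWarnings(min(.data$points, na.rm = TRUE)),
      max = suppressWarnings(max(.data$points, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$attribute, .attribute_ids()))

  rating <- dplyr::bind_rows(
    tibble(measure = "availability",
           category = c(sprintf(">= %d/%d", config$availability_threshold,
                                config$n_attributes),
                        sprintf("< %d/%d", config$availability_threshold,
                                config$n_attributes)),
           n = c(sum(ratings$availability_sufficient),
                 sum(!ratings$availability_sufficient))),
    tibble(measure = "quality",
           category = c(sprintf(">= %g", config$quality_threshold),
                        sprintf("< %g", config$quality_threshold)),
           n = c(sum(ratings$quality_sufficient, na.rm = TRUE),
                 sum(!ratings$quality_sufficient, na.rm = TRUE))),
    tibble(measure = "interval",
           category = rev(config$interval_labels),
           n = map_int(rev(config$interval_labels),
                       ~ sum(ratings$interval == .x, na.rm = TRUE)))
  ) |>
    dplyr::mutate(pct = pct_of(.data$n, n),
                  cell = format_count_pct(.data$n, .data$pct))

  overall <- tibble(
    mean = round_half_up(mean(ratings$overall_score, na.rm = TRUE), 1),
    sd = if (n > 1) round_half_up(sd(ratings$overall_score, na.rm = TRUE), 1)
         else NA_real_,
    min = min(ratings$overall_score, na.rm = TRUE),
    max = max(ratings$overall_score, na.rm = TRUE)
  )

  structure(
    list(n = n, screening = screening, grades = grades, points = points,
         rating = rating, overall = overall),
    class = "rih_summary"
  )
}

#' @export
print.rih_summary <- function(x, ...) {
  cat("Sample of", x$n, "innovation(s)\n")
  if (!is.null(x$screening)) {
    cat("\n-- Screening step (include / exclude) --\n")
    scr <- x$screening |>
      dplyr::transmute(criterion = .data$criterion,
                       include = format_count_pct(.data$n_include, .data$pct_include),
                       exclude = format_count_pct(.data$n_exclude, .data$pct_exclude))
    print(as.data.frame(scr), row.names = FALSE)
  }
  cat("\n-- Assessment step (grade counts, % of documented) --\n")
  wide <- x$grades |>
    dplyr::select("attribute", "grade", "cell") |>
    tidyr::pivot_wider(names_from = "grade", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  cat("\n-- Rating step --\n")
  print(as.data.frame(x$rating[c("measure", "category", "cell")]),
        row.names = FALSE)
  cat("\nOverall score: mean", x$overall$mean, "SD", x$overall$sd,
      "min", x$overall$min, "max", x$overall$max, "\n")
  invisible(x)
}
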