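#' Broom-style tidiers
#'
#' `tidy()` returns the per-unit estimates of a result object as a plain
#' tibble; `glance()` condenses it to a one-row overview.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name rih-tidiers
NULL

#' @rdname rih-tidiers
#' @export
tidy.rih_ratings <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname rih-tidiers
#' @export
glance.rih_ratings <- function(x, ...) {
  tibble(
    n_innovations = nrow(x),
    n_proceed = sum(x$proceed, na.rm = TRUE),
    n_meaningful = sum(x$meaningful, na.rm = TRUE),
    mean_overall = round_half_up(mean(x$overall_score, na.rm = TRUE), 1),
    sd_overall = if (nrow(x) > 1)
      round_half_up(sd(x$overall_score, na.rm = TRUE), 1) else NA_real_,
    min_overall = min(x$overall_score, na.rm = TRUE),
    max_overall = max(x$overall_score, na.rm = TRUE)
  )
}

#' @rdname rih-tidiers
#' @export
tidy.rih_agreement <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname rih-tidiers
#' @export
glance.rih_agreement <- function(x, ...) {
  tibble(
    n_scales = nrow(x),
    min_coefficient = min(x$coefficient),
    max_coefficient = max(x$coefficient),
    n_almost_perfect = sum(x$benchmark == "Almost perfect"),
    weights = attr(x, "weights") %||% NA_character_
  )
}

#' @rdname rih-tidiers
#' @export
tidy.rih_summary <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$screening)) {
      x$screening |>
        tidyr::pivot_longer(-"criterion", names_to = "statistic",
                            values_to = "value") |>
        dplyr::transmute(section = "screening", unit = .data$criterion,
                         statistic = .data$statistic,
                         value = as.numeric(.data$value))
    },
    x$grades |>
      dplyr::transmute(section = "grades",
                       unit = paste(.data$attribute, .data$grade, sep = ":"),
                       statistic = "pct_documented",
                       value = as.numeric(.data$pct)),
    x$points |>
      tidyr::pivot_longer(-"attribute", names_to = "statistic",
                          values_to = "value") |>
      dplyr::transmute(section = "points", unit = .data$attribute,
                       statistic = .data$statistic,
                       value = as.numeric(.data$value)),
    x$rating |>
      dplyr::transmute(section = "rating",
                       unit = paste(.data$measure, .data$category, sep = ":"),
                       statistic = "pct", value = as.numeric(.data$pct))
  )
}

#' @rdname rih-tidiers
#' @export
tidy.rih_correlation <- function(x, ...) {
  as_tibble(unclass(x))
}
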