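#' Screening step: should an innovation proceed to assessment?
#'
#' The screening step applies four dichotomous gates. An innovation
#' proceeds only when both inclusion criteria (determinants of health,
#' innovativeness) are answered "yes" and both exclusion criteria
#' (unavailability, corporate social irresponsibility) are answered "no".
#' Every failed criterion is listed as a reason for exclusion.
#'
#' @param scorecards Long scorecard tibble (see [scorecard()]).
#' @return A tibble with one row per innovation: the four answers, a
#'   logical `proceed`, and a list-column `reasons` naming each failed
#'   criterion (empty when proceeding).
#' @examples
#' sc <- scorecard("x", rep("A", 9),
#'                 screening = c("yes", "yes", "yes", "no"))
#' rih_screen(sc)
#' @export
rih_screen <- function(scorecards) {
  scorecards <- validate_scorecards(scorecards)
  crits <- rih_screening_criteria()

  wide <- scorecards |>
    dplyr::filter(.data$criterion_or_attribute %in% crits$criterion) |>
    dplyr::select("innovation_id", "criterion_or_attribute", "value") |>
    tidyr::pivot_wider(names_from = "criterion_or_attribute",
                       values_from = "value")

  absent <- setdiff(crits$criterion, names(wide))
  if (length(absent) > 0) {
    abort(paste0("incomplete screening: criteria never answered: ",
                 paste(absent, collapse = ", ")),
          class = "rih_incomplete_screening")
  }
  ans <- as.matrix(wide[crits$criterion])
  if (anyNA(ans)) {
    bad <- wide$innovation_id[apply(is.na(ans), 1, any)]
    abort(paste0("incomplete screening for innovation(s): ",
                 paste(bad, collapse = ", ")),
          class = "rih_incomplete_screening")
  }

  ok <- sweep(ans, 2, crits$include_answer, `==`)
  wide$proceed <- apply(ok, 1, all)
  wide$reasons <- apply(ok, 1, function(r) crits$criterion[!r],
                        simplify = FALSE)
  as_tibble(wide)
}
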