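#' The nine assessment attributes and their value domains
#'
#' The instrument assesses an innovation on nine attributes organised in
#' five value domains: population health (health relevance; ethical, legal
#' and social issues; health inequalities), health system (inclusiveness,
#' responsiveness, level and intensity of care), economic (frugality),
#' organizational (business model) and environmental (eco-responsibility).
#'
#' @return A tibble with columns `attribute` (machine id), `domain` and
#'   `label` (display name), in canonical scorecard order.
#' @examples
#' rih_attributes()
#' @export
rih_attributes <- function() {
  tibble(
    attribute = c(
      "health_relevance", "elsis", "health_inequalities",
      "inclusiveness", "responsiveness", "level_intensity_of_care",
      "frugality", "business_model", "eco_responsibility"
    ),
    domain = c(
      "population_health", "population_health", "population_health",
      "health_system", "health_system", "health_system",
      "economic", "organizational", "environmental"
    ),
    label = c(
      "Health relevance", "ELSIs", "Health inequalities",
      "Inclusiveness", "Responsiveness", "Level and intensity of care",
      "Frugality", "Business model", "Eco-responsibility"
    )
  )
}

#' The four dichotomous screening criteria
#'
#' Two inclusion criteria (determinants of health, innovativeness) must be
#' answered "yes" and two exclusion criteria (unavailability, corporate
#' social irresponsibility) must be answered "no" for an innovation to
#' proceed to assessment.
#'
#' @return A tibble with columns `criterion`, `role`
#'   (`"inclusion"`/`"exclusion"`), `include_answer` (the answer compatible
#'   with proceeding) and `label`.
#' @examples
#' rih_screening_criteria()
#' @export
rih_screening_criteria <- function() {
  tibble(
    criterion = c(
      "determinants_of_health", "innovativeness",
      "unavailability", "corporate_social_irresponsibility"
    ),
    role = c("inclusion", "inclusion", "exclusion", "exclusion"),
    include_answer = c("yes", "yes", "no", "no"),
    label = c(
      "Determinants of health", "Innovativeness",
      "Unavailability", "Corporate social irresponsibility"
    )
  )
}

.attribute_ids <- function() rih_attributes()$attribute
.criterion_ids <- function() rih_screening_criteria()$criterion
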