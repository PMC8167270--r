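#' Build a scorecard in the long tabular format
#'
#' A scorecard records one innovation's four screening answers and its nine
#' attribute assessments (grade plus best information source). The long
#' format — one row per criterion or attribute — is the package's exchange
#' format: it pipes directly into [rih_screen()], [rih_rate()] and
#' [rih_summarize()], and round-trips through [write_scorecards()] /
#' [read_scorecards()].
#'
#' @param innovation_id Identifier for the innovation.
#' @param grades Named character vector of grades (`"A"`-`"D"`, `NA` for
#'   undocumented), names being attribute ids as in [rih_attributes()].
#'   Unnamed vectors of length 9 are taken in canonical attribute order.
#' @param sources Source types per attribute: a named (or length-9
#'   positional) vector of best types in `1:3`, or a list of type vectors
#'   per attribute, in which case [best_source()] is applied. Default: all
#'   `NA` (no sources recorded).
#' @param screening Named character vector of `"yes"`/`"no"` answers to the
#'   four screening criteria. Defaults to the all-clear pattern.
#' @param region Free-text context of use; the degree of responsibility of
#'   an innovation is always judged relative to where it is deployed.
#' @return A tibble with columns `innovation_id`, `region`,
#'   `criterion_or_attribute`, `value`, `source_type`.
#' @examples
#' scorecard("demo", grades = rep("A", 9), sources = rep(3, 9))
#' @export
scorecard <- function(innovation_id,
                      grades,
                      sources = NULL,
                      screening = c(determinants_of_health = "yes",
                                    innovativeness = "yes",
                                    unavailability = "no",
                                    corporate_social_irresponsibility = "no"),
                      region = NA_character_) {
  attrs <- .attribute_ids()
  crits <- .criterion_ids()

  grades <- .name_by_position(grades, attrs, "grades")
  if (!setequal(names(grades), attrs)) {
    abort(paste0("`grades` must cover exactly the 9 attributes; missing: ",
                 paste(setdiff(attrs, names(grades)), collapse = ", ")))
  }
  if (is.null(sources)) sources <- setNames(rep(NA_integer_, 9), attrs)
  if (is.list(sources)) {
    sources <- setNames(best_source(sources), names(sources) %||% attrs)
  }
  sources <- .name_by_position(sources, attrs, "sources")

  screening <- .name_by_position(screening, crits, "screening")
  if (!setequal(names(screening), crits)) {
    abort("`screening` must answer exactly the 4 screening criteria.")
  }

  out <- dplyr::bind_rows(
    tibble(
      criterion_or_attribute = crits,
      value = tolower(as.character(screening[crits])),
      source_type = NA_integer_
    ),
    tibble(
      criterion_or_attribute = attrs,
      value = toupper(as.character(grades[attrs])),
      source_type = as.integer(sources[attrs])
    )
  )
  out <- dplyr::mutate(out,
                       innovation_id = as.character(innovation_id),
                       region = as.character(region),
                       .before = 1)
  validate_scorecards(out)
}

.name_by_position <- function(x, ids, what) {
  if (is.null(names(x))) {
    if (length(x) != length(ids)) {
      abort(paste0("unnamed `", what, "` must have length ", length(ids)))
    }
    names(x) <- ids
  }
  x
}

#' Validate a long scorecard table
#'
#' Checks the scorecard exchange format: known criterion/attribute names,
#' screening answers in yes/no, grades in A-D (or missing), source types in
#' 1-3 (or missing), and no duplicated criterion or attribute within an
#' innovation. Violations are reported with the offending row numbers.
#'
#' @param data Long scorecard tibble (see [scorecard()]).
#' @return `data`, invisibly validated (returned as a tibble).
#' @export
validate_scorecards <- function(data) {
  required <- c("innovation_id", "criterion_or_attribute", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("scorecard data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (!"region" %in% names(data)) data$region <- NA_character_
  if (!"source_type" %in% names(data)) data$source_type <- NA_integer_
  data$source_type <- as.integer(data$source_type)

  attrs <- .attribute_ids()
  crits <- .criterion_ids()
  row <- seq_len(nrow(data))

  known <- data$criterion_or_attribute %in% c(attrs, crits)
  if (!all(known)) {
    abort(paste0(
      "unknown criterion_or_attribute in row(s) ",
      paste(row[!known], collapse = ", "), ": ",
      paste(unique(data$criterion_or_attribute[!known]), collapse = ", ")
    ))
  }

  is_crit <- data$criterion_or_attribute %in% crits
  bad_ans <- is_crit & !is.na(data$value) &
    !tolower(data$value) %in% c("yes", "no")
  if (any(bad_ans)) {
    abort(paste0("screening answers must be yes/no; bad row(s): ",
                 paste(row[bad_ans], collapse = ", ")))
  }
  bad_grade <- !is_crit & !is.na(data$value) &
    !toupper(data$value) %in% c("A", "B", "C", "D")
  if (any(bad_grade)) {
    abort(paste0("grades must be A, B, C, D or NA; bad row(s): ",
                 paste(row[bad_grade], collapse = ", ")))
  }
  bad_src <- !is.na(data$source_type) & !data$source_type %in% 1:3
  if (any(bad_src)) {
    abort(paste0("source_type must be 1, 2, 3 or NA; bad row(s): ",
                 paste(row[bad_src], collapse = ", ")))
  }

  dup <- data |>
    dplyr::count(.data$innovation_id, .data$criterion_or_attribute) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicated criterion/attribute per innovation: ",
      paste(sprintf("%s:%s", dup$innovation_id, dup$criterion_or_attribute),
            collapse = ", ")
    ))
  }

  data |>
    dplyr::mutate(
      value = dplyr::if_else(.data$criterion_or_attribute %in% crits,
                             tolower(.data$value), toupper(.data$value))
    )
}
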