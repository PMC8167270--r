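#' Read and write scorecards in the long CSV dialect
#'
#' The exchange format is a UTF-8 CSV with a header and the columns
#' `innovation_id`, `region`, `criterion_or_attribute`, `value`,
#' `source_type`: screening rows carry `yes`/`no` in `value`, attribute
#' rows a grade `A`-`D` (empty for undocumented) and the best source type
#' `1`-`3` (empty if none). Reading validates the file and reports
#' malformed rows with their line numbers.
#'
#' @param path File path.
#' @param config An [rih_config()] object (reserved for scale overrides).
#' @return `read_scorecards()`: a validated long scorecard tibble;
#'   `write_scorecards()`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_scorecards(scorecard("x", rep("A", 9)), f)
#' read_scorecards(f)
#' @export
read_scorecards <- function(path, config = rih_config()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      innovation_id = readr::col_character(),
      region = readr::col_character(),
      criterion_or_attribute = readr::col_character(),
      value = readr::col_character(),
      source_type = readr::col_integer()
    )
  )
  missing_cols <- setdiff(c("innovation_id", "criterion_or_attribute", "value"),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("scorecard CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_scorecards(raw)
}

#' @param data Long scorecard tibble.
#' @rdname read_scorecards
#' @export
write_scorecards <- function(data, path) {
  data <- validate_scorecards(data)
  readr::write_csv(
    data[c("innovation_id", "region", "criterion_or_attribute",
           "value", "source_type")],
    path, na = ""
  )
  invisible(path)
}

#' Read a two-rater ratings table from CSV
#'
#' Expects columns `item_id`, `attribute`, `rater_id`, `value` (grade
#' letter, yes/no answer or interval bin; empty cells are missing), and
#' exactly two distinct rater ids. The result pipes into
#' [rih_agreement()].
#'
#' @param path File path.
#' @return A long ratings tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      item_id = readr::col_character(),
      attribute = readr::col_character(),
      rater_id = readr::col_character(),
      value = readr::col_character()
    )
  )
  missing_cols <- setdiff(c("item_id", "attribute", "rater_id", "value"),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("ratings CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n_raters <- length(unique(raw$rater_id))
  if (n_raters != 2) {
    abort(paste0("exactly 2 raters required, found ", n_raters))
  }
  raw
}

#' Machine-readable JSON report
#'
#' Serializes rating, agreement or sample-summary results to JSON with a
#' deterministic key order (diff-stable across runs) and numbers at the
#' conventional reporting precision: scores to one decimal, coefficients
#' to three decimals, percentages as integers.
#'
#' @param x An `rih_ratings`, `rih_agreement` or `rih_summary` object.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @param ... Unused.
#' @return The JSON string (invisibly when written to `path`).
#' @export
rih_report <- function(x, path = NULL, ...) {
  UseMethod("rih_report")
}

.emit_json <- function(obj, path) {
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
rih_report.rih_ratings <- function(x, path = NULL, ...) {
  if (nrow(x) == 0) abort("cannot report an empty rating table")
  details <- attr(x, "details")
  innovations <- map(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    det <- details[details$innovation_id == row$innovation_id, ]
    list(
      innovation_id = row$innovation_id,
      region = row$region,
      proceed = row$proceed,
      n_documented = row$n_documented,
      availability_sufficient = row$availability_sufficient,
      quality_mean = row$quality_mean,
      quality_sufficient = row$quality_sufficient,
      overall_score = row$overall_score,
      interval = row$interval,
      meaningful = row$meaningful,
      attributes = map(seq_len(nrow(det)), function(j) {
        list(attribute = det$attribute[j],
             grade = det$grade[j],
             points = det$points[j],
             best_source = det$best_source[j])
      })
    )
  })
  .emit_json(list(canonical = isTRUE(attr(x, "canonical")),
                  innovations = innovations), path)
}

#' @export
rih_report.rih_agreement <- function(x, path = NULL, ...) {
  if (nrow(x) == 0) abort("cannot report an empty agreement table")
  rows <- map(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    list(
      attribute = if ("attribute" %in% names(row)) row$attribute else NULL,
      n = row$n_used,
      percent_agreement = as.integer(round_half_up(100 * row$pa)),
      coefficient = round_half_up(row$coefficient, 3),
      se = round_half_up(row$se, 5),
      ci_low = round_half_up(row$ci_low, 3),
      ci_high = round_half_up(row$ci_high, 3),
      p_value = if (is.na(row$p_value)) "n/a" else signif(row$p_value, 3),
      benchmark = row$benchmark
    )
  })
  .emit_json(list(weights = attr(x, "weights"),
                  conf_level = attr(x, "conf_level"),
                  estimates = rows), path)
}

#' @export
rih_report.rih_summary <- function(x, path = NULL, ...) {
  obj <- list(
    n = x$n,
    screening = if (is.null(x$screening)) NULL else
      unclass_rows(x$screening),
    grades = unclass_rows(x$grades),
    points = unclass_rows(x$points),
    rating = unclass_rows(x$rating),
    overall = as.list(x$overall)
  )
  .emit_json(obj, path)
}

unclass_rows <- function(df) {
  map(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}
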