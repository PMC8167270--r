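#' Convert attribute grades to responsibility points
#'
#' Grades map to points on a deliberately non-equidistant scale: A (high
#' degree of responsibility) is worth 5 points, B (moderate) 4, C (low) 2
#' and D (no particular signs of responsibility) 1. The gap between B and C
#' separates innovations with clear responsibility features from the rest.
#'
#' @param grade Character vector of grades (`"A"`-`"D"`).
#' @param config An [rih_config()] object.
#' @return Integer-valued numeric vector of points.
#' @seealso [points_to_grade()] for the inverse map.
#' @examples
#' grade_to_points(c("A", "C"))
#' @export
grade_to_points <- function(grade, config = rih_config()) {
  g <- toupper(as.character(grade))
  if (anyNA(g)) {
    abort("undocumented attribute: grade is missing (cannot assign points)",
          class = "rih_undocumented")
  }
  bad <- !g %in% names(config$grade_points)
  if (any(bad)) {
    abort(paste0("unknown grade(s): ", paste(unique(g[bad]), collapse = ", ")))
  }
  unname(config$grade_points[g])
}

# NA-tolerant variant used internally by the rating step
grade_points_na <- function(grade, config = rih_config()) {
  g <- toupper(as.character(grade))
  out <- rep(NA_real_, length(g))
  ok <- !is.na(g)
  if (any(ok)) out[ok] <- grade_to_points(g[ok], config)
  out
}

#' Convert points back to grades
#'
#' Inverse of [grade_to_points()]; useful for building scorecards from
#' published point rows.
#'
#' @param points Numeric vector of points (5, 4, 2 or 1 by default);
#'   `NA` passes through as `NA` (undocumented attribute).
#' @inheritParams grade_to_points
#' @return Character vector of grades.
#' @examples
#' points_to_grade(c(5, 4, NA, 1))
#' @export
points_to_grade <- function(points, config = rih_config()) {
  inv <- setNames(names(config$grade_points), config$grade_points)
  out <- inv[as.character(points)]
  bad <- !is.na(points) & is.na(out)
  if (any(bad)) {
    abort(paste0("point value(s) with no grade: ",
                 paste(unique(points[bad]), collapse = ", ")))
  }
  unname(out)
}

#' Points carried by information-source types
#'
#' Source quality is a three-level hierarchy and the points equal the type
#' number: type 1 (producer documentation) 1 point, type 2 (institutional
#' and regulatory reports) 2 points, type 3 (peer-reviewed literature) 3
#' points.
#'
#' @param type Integer vector of source types in `1:3`; `NA` allowed.
#' @param config An [rih_config()] object.
#' @return Numeric vector of points (`NA` where type is `NA`).
#' @examples
#' source_points(c(1, 3, NA))
#' @export
source_points <- function(type, config = rih_config()) {
  t_chr <- as.character(type)
  out <- rep(NA_real_, length(type))
  ok <- !is.na(type)
  bad <- ok & !t_chr %in% names(config$source_points)
  if (any(bad)) {
    abort(paste0("unknown source type(s): ",
                 paste(unique(type[bad]), collapse = ", ")))
  }
  out[ok] <- unname(config$source_points[t_chr[ok]])
  out
}

#' Best (highest-quality) source among those used for an attribute
#'
#' When more than one type of information is used to score an attribute,
#' the source of highest quality is the one reported. An empty set of
#' sources (or all-missing) yields `NA`: the attribute's quality cannot be
#' assessed.
#'
#' @param sources Integer vector of source types for one attribute, or a
#'   list of such vectors (one element per attribute).
#' @return Integer vector: the maximum non-missing type per element, `NA`
#'   where no source is recorded.
#' @examples
#' best_source(c(1, 3, 2))
#' best_source(list(c(1, 3, 2), 2, integer(0)))
#' @export
best_source <- function(sources) {
  if (!is.list(sources)) sources <- list(sources)
  map_int(sources, function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0) return(NA_integer_)
    if (!all(s %in% 1:3)) {
      abort(paste0("source types must be 1, 2 or 3; got ",
                   paste(unique(s[!s %in% 1:3]), collapse = ", ")))
    }
    as.integer(max(s))
  })
}
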