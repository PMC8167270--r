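#' Pearson correlation between two raters' continuous scores
#'
#' The product-moment correlation estimates the strength and direction of
#' the linear relationship between the two raters' overall scores — a
#' complement to agreement coefficients, which reward identity rather than
#' linearity. Reports the two-sided test against zero and the Hinkle
#' rule-of-thumb interpretation of the magnitude.
#'
#' @param x,y Numeric score vectors of equal length (at least 3), e.g. the
#'   two raters' overall scores across innovations; pairs with a missing
#'   value are dropped.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble of class `rih_correlation`: `n`, `r`,
#'   `ci_low`, `ci_high`, `p_value`, `interpretation`.
#' @examples
#' rih_correlation(c(4.6, 3.6, 2.3, 4.1), c(4.5, 3.8, 2.1, 4.2))
#' @export
rih_correlation <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: a score vector is constant",
          class = "rih_constant")
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  out <- tibble(
    n = length(x),
    r = unname(ct$estimate),
    ci_low = ct$conf.int[1],
    ci_high = ct$conf.int[2],
    p_value = ct$p.value,
    interpretation = hinkle_interpretation(unname(ct$estimate))
  )
  structure(out, class = c("rih_correlation", class(out)),
            conf_level = conf_level)
}
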