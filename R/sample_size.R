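#' Sample size for a two-rater agreement study
#'
#' Plans the number of items needed so that the percent agreement between
#' two raters is estimated with a prescribed precision: the smallest `n`
#' such that the worst-case normal-approximation confidence half-width of
#' a proportion, `z * sqrt(0.25 / n)`, does not exceed the error margin
#' (the variance of a proportion is maximal at 0.5, so the bound holds
#' whatever the true agreement).
#'
#' @param error_margin Half-width of the confidence interval to tolerate,
#'   strictly between 0 and 1 (e.g. `0.20`).
#' @param conf_level Confidence level (default 0.95).
#' @return The smallest integer sample size meeting the bound.
#' @examples
#' agreement_sample_size(0.20) # 25
#' agreement_sample_size(0.10) # 97
#' @export
agreement_sample_size <- function(error_margin, conf_level = 0.95) {
  if (length(error_margin) != 1 || is.na(error_margin) ||
      error_margin <= 0 || error_margin >= 1) {
    abort("`error_margin` must be a single number strictly between 0 and 1")
  }
  if (conf_level <= 0 || conf_level >= 1) {
    abort("`conf_level` must lie strictly between 0 and 1")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  half_width <- function(n) z * sqrt(0.25 / n)
  n <- max(1, floor((z * 0.5 / error_margin)^2))
  while (half_width(n) > error_margin + 1e-12) n <- n + 1
  while (n > 1 && half_width(n - 1) <= error_margin + 1e-12) n <- n - 1
  as.integer(n)
}
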