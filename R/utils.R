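#' Round half away from zero
#'
#' Base `round()` rounds exact halves to the nearest even digit. Scorecard
#' arithmetic instead uses the everyday convention that a half always rounds
#' up (away from zero): a raw overall score of 2.25 prints as 2.3, not 2.2.
#' A small guard absorbs binary floating-point representation error so that
#' values like `0.1 + 0.2` round as the decimal they denote.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(2.25, 2.35, 16 / 7), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  z <- x * p
  sign(z) * floor(abs(z) + 0.5 + 1e-9) / p
}

# "21 (84%)" cell formatting used throughout sample summaries
format_count_pct <- function(n, pct) {
  ifelse(is.na(n), NA_character_, sprintf("%d (%d%%)", n, as.integer(pct)))
}

# integer percentage of a count over a denominator, half-up
pct_of <- function(n, denom) {
  ifelse(denom > 0, round_half_up(100 * n / denom), NA_real_)
}

# Simulation calls that take a seed must not disturb the caller's RNG
# stream: snapshot .Random.seed, reseed, and restore via on.exit().
snapshot_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
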