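# Shared rank coding for a pair of rating vectors.
# Categories come from (in order of precedence) the `categories` argument,
# factor levels, or the sorted unique values observed in either vector.
as_rank_pair <- function(x, y, categories = NULL) {
  if (length(x) != length(y)) {
    abort("the two rating vectors must have equal length")
  }
  if (is.null(categories)) {
    if (is.factor(x) || is.factor(y)) {
      lx <- if (is.factor(x)) levels(x) else NULL
      ly <- if (is.factor(y)) levels(y) else NULL
      if (!is.null(lx) && !is.null(ly) && !identical(lx, ly)) {
        abort("the two factors must share identical levels")
      }
      categories <- lx %||% ly
    } else if (is.numeric(x) && is.numeric(y) &&
               all(c(x, y) %% 1 == 0, na.rm = TRUE)) {
      categories <- as.character(seq_len(max(c(x, y), na.rm = TRUE)))
    } else {
      categories <- sort(unique(stats::na.omit(c(as.character(x),
                                                 as.character(y)))))
    }
  }
  categories <- as.character(categories)
  r1 <- match(as.character(x), categories)
  r2 <- match(as.character(y), categories)
  bad <- (!is.na(x) & is.na(r1)) | (!is.na(y) & is.na(r2))
  if (any(bad)) {
    abort(paste0("rating(s) outside the declared categories at position(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  list(r1 = r1, r2 = r2, categories = categories)
}

#' Weighted percent agreement between two raters
#'
#' The non-adjusted agreement index: the mean, over items rated by both
#' raters (pairwise deletion), of the weight earned by the pair of
#' categories chosen. With identity weights this is the raw proportion of
#' exact agreements; with quadratic weights, near-miss disagreements earn
#' partial credit.
#'
#' @param x,y Ratings by the two raters: factors, characters or integer
#'   ranks, with `NA` for missing cells.
#' @param weights `"identity"`, `"quadratic"`, or a custom symmetric weight
#'   matrix (see [quadratic_weights()]).
#' @param categories Optional explicit category levels, in scale order;
#'   needed when not all categories are observed or the default ordering
#'   is wrong.
#' @return A single number in `[0, 1]`.
#' @examples
#' percent_agreement(c(1, 1, 2, 1), c(1, 1, 2, 2)) # 3/4
#' @export
percent_agreement <- function(x, y, weights = "identity", categories = NULL) {
  rk <- as_rank_pair(x, y, categories)
  keep <- !is.na(rk$r1) & !is.na(rk$r2)
  if (!any(keep)) {
    abort("no items rated by both raters", class = "rih_no_pairs")
  }
  W <- resolve_weights(weights, length(rk$categories))
  mean(W[cbind(rk$r1[keep], rk$r2[keep])])
}

# Core two-rater AC estimator with the linearized variance.
# pe = Tw / (q (q - 1)) * sum_k pi_k (1 - pi_k), with pi_k the average
# proportion of the two raters classifying an item into category k,
# estimated from pairwise-complete items. The per-item influence values
# carry the correction for the estimated chance-agreement component; no
# finite-population correction is applied (innovations are treated as
# sampled from an unlimited universe).
ac_core <- function(r1, r2, W, conf_level = 0.95) {
  keep <- !is.na(r1) & !is.na(r2)
  r1 <- r1[keep]
  r2 <- r2[keep]
  n <- length(r1)
  if (n < 1) abort("no items rated by both raters", class = "rih_no_pairs")
  q <- nrow(W)

  pa_i <- W[cbind(r1, r2)]
  pa <- mean(pa_i)
  pik <- (tabulate(r1, q) + tabulate(r2, q)) / (2 * n)
  tw <- sum(W)
  pe <- tw / (q * (q - 1)) * sum(pik * (1 - pik))
  if (pe >= 1 - 1e-12) {
    abort("coefficient undefined: chance agreement saturates at 1",
          class = "rih_degenerate")
  }
  coef <- (pa - pe) / (1 - pe)

  se <- ci_low <- ci_high <- p_value <- NA_real_
  if (n >= 2) {
    coef_i <- (pa_i - pe) / (1 - pe)
    pe_i <- tw / (q * (q - 1)) *
      ((1 - pik[r1]) + (1 - pik[r2])) / 2
    infl <- coef_i - 2 * (1 - coef) * (pe_i - pe) / (1 - pe)
    v <- sum((infl - coef)^2) / (n * (n - 1))
    se <- sqrt(max(v, 0))
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci_low <- max(coef - tq * se, -1)
    ci_high <- min(coef + tq * se, 1)
    p_value <- if (se > 0) 2 * pt(-abs(coef / se), df = n - 1) else NA_real_
  }
  list(n_used = n, pa = pa, pe = pe, coefficient = coef, se = se,
       ci_low = ci_low, ci_high = ci_high, p_value = p_value)
}

#' Gwet's AC1/AC2 chance-corrected agreement coefficient
#'
#' Estimates the agreement between two raters corrected for the agreement
#' expected by chance, using the paradox-resistant AC family. Chance
#' agreement is `pe = Tw / (q (q - 1)) * sum_k pi_k (1 - pi_k)`, where `Tw`
#' is the sum of all weights and `pi_k` the average proportion of raters
#' classifying an item into category `k`; the coefficient is
#' `(pa - pe) / (1 - pe)`. Identity weights give AC1 (nominal scales);
#' quadratic weights give AC2 (ordinal scales). Standard errors come from
#' the two-rater linearization (per-item influence values corrected for the
#' estimated chance component), confidence limits use Student's t with
#' `n - 1` degrees of freedom and are clipped to `[-1, 1]`, and the p-value
#' tests the coefficient against zero (two-sided). Perfect agreement yields
#' coefficient 1 with a zero standard error and no p-value.
#'
#' Items missing either rating are dropped (pairwise deletion), and the
#' category proportions are estimated from the retained items.
#'
#' @inheritParams percent_agreement
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble of class `rih_agreement`: `n_used`, `pa`, `pe`,
#'   `coefficient`, `se`, `ci_low`, `ci_high`, `p_value`, `benchmark`
#'   (Landis-Koch label).
#' @examples
#' gwet_ac(c(1, 1, 2, 1), c(1, 1, 2, 2), weights = "identity")
#' @export
gwet_ac <- function(x, y, weights = "identity", categories = NULL,
                    conf_level = 0.95) {
  rk <- as_rank_pair(x, y, categories)
  W <- resolve_weights(weights, length(rk$categories))
  est <- ac_core(rk$r1, rk$r2, W, conf_level)
  out <- as_tibble(est[c("n_used", "pa", "pe", "coefficient", "se",
                         "ci_low", "ci_high", "p_value")])
  out$benchmark <- landis_koch(out$coefficient)
  structure(out, class = c("rih_agreement", class(out)),
            weights = if (is.character(weights)) weights else "custom",
            conf_level = conf_level)
}

#' Inter-rater agreement for a long two-rater ratings table
#'
#' Data-frame front end for [gwet_ac()]: takes ratings in long form (one
#' row per item, attribute and rater) and returns one agreement estimate
#' per attribute, pairwise-deleting items either rater left unrated. This
#' reproduces the standard reliability-report shape: N, percent agreement,
#' coefficient, SE, 95% CI, p-value and Landis-Koch benchmark per
#' attribute.
#'
#' @param data Tibble with columns `item_id`, `attribute`, `rater_id`,
#'   `value`; exactly two distinct `rater_id`s are required.
#' @param weights `"quadratic"` (default, for ordinal grades) or
#'   `"identity"` (for nominal screening answers), or a custom matrix.
#' @param categories Optional category levels in scale order, applied to
#'   every attribute; defaults per attribute as in [gwet_ac()] (sorted
#'   unique values, so grades A < B < C < D and answers no < yes work
#'   unaided).
#' @param conf_level Confidence level.
#' @return A tibble of class `rih_agreement`, one row per attribute, with
#'   the columns of [gwet_ac()] plus `attribute`.
#' @examples
#' tbl <- simulate_rating_pair(n_items = 25, seed = 1)
#' rih_agreement(pair_to_long(tbl, attribute = "demo"))
#' @export
rih_agreement <- function(data, weights = "quadratic", categories = NULL,
                          conf_level = 0.95) {
  required <- c("item_id", "attribute", "rater_id", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("ratings data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raters <- sort(unique(data$rater_id))
  if (length(raters) != 2) {
    abort(paste0("exactly 2 raters required, found ", length(raters)))
  }
  out <- data |>
    dplyr::group_by(.data$attribute) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, id_cols = "item_id",
                                 names_from = "rater_id",
                                 values_from = "value")
      gwet_ac(wide[[raters[1]]], wide[[raters[2]]],
              weights = weights, categories = categories,
              conf_level = conf_level)
    }) |>
    dplyr::ungroup()
  structure(out, class = c("rih_agreement", class(out)),
            weights = if (is.character(weights)) weights else "custom",
            conf_level = conf_level)
}

#' @export
print.rih_agreement <- function(x, ...) {
  df <- as.data.frame(x)
  fmt <- data.frame(
    N = df$n_used,
    `Percent Agreement` = sprintf("%d%%", as.integer(round_half_up(100 * df$pa))),
    Coefficient = formatC(round_half_up(df$coefficient, 3), digits = 3,
                          format = "fg"),
    `Standard Error` = sprintf("%.5f", df$se),
    `95% CI` = sprintf("%s to %s",
                       formatC(round_half_up(df$ci_low, 3), digits = 3,
                               format = "fg"),
                       formatC(round_half_up(df$ci_high, 3), digits = 3,
                               format = "fg")),
    `P Value` = ifelse(is.na(df$p_value), "n/a",
                       ifelse(df$p_value < 0.001, "<.001",
                              sub("^0", "", sprintf("%.3f", df$p_value)))),
    Benchmark = df$benchmark,
    check.names = FALSE
  )
  if ("attribute" %in% names(df)) {
    fmt <- cbind(Attribute = df$attribute, fmt)
  }
  cat("Inter-rater agreement (Gwet's AC,", attr(x, "weights"), "weights)\n")
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Reshape a wide rater pair to the long ratings format
#'
#' @param pair Tibble with columns `item_id`, `rater_1`, `rater_2` (as
#'   returned by [simulate_rating_pair()]).
#' @param attribute Attribute name to stamp on the rows.
#' @return Long tibble with columns `item_id`, `attribute`, `rater_id`,
#'   `value`.
#' @export
pair_to_long <- function(pair, attribute = "attribute") {
  pair |>
    dplyr::select("item_id", "rater_1", "rater_2") |>
    tidyr::pivot_longer(c("rater_1", "rater_2"),
                        names_to = "rater_id", values_to = "value") |>
    dplyr::mutate(attribute = attribute, .after = "item_id")
}
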