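#' Plot methods
#'
#' `autoplot()` methods give each result type its standard display:
#'
#' * `rih_ratings`: per-innovation overall scores as bars coloured by
#'   interval label, with meaningfulness marked;
#' * `rih_agreement`: a forest-style plot of agreement coefficients with
#'   their confidence intervals;
#' * `rih_summary`: the per-attribute grade distribution as stacked
#'   percentage bars.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name rih-plots
NULL

#' @rdname rih-plots
#' @export
autoplot.rih_ratings <- function(object, ...) {
  df <- as_tibble(object)
  df$interval <- factor(df$interval, levels = rih_config()$interval_labels)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$innovation_id, .data$overall_score),
    y = .data$overall_score, fill = .data$interval
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$meaningful %in% TRUE, "", "*")),
      vjust = -0.3, na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 5)) +
    ggplot2::labs(x = NULL, y = "Overall responsibility score",
                  fill = "Interval",
                  caption = "* overall score not meaningful") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname rih-plots
#' @export
autoplot.rih_agreement <- function(object, ...) {
  df <- as_tibble(object)
  if (!"attribute" %in% names(df)) df$attribute <- "overall"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$coefficient,
    y = stats::reorder(.data$attribute, .data$coefficient)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$benchmark), size = 2) +
    ggplot2::xlim(min(0, df$ci_low), 1) +
    ggplot2::labs(x = "Gwet's AC coefficient", y = NULL,
                  colour = "Benchmark") +
    ggplot2::theme_minimal()
}

#' @rdname rih-plots
#' @export
autoplot.rih_summary <- function(object, ...) {
  df <- object$grades
  df$attribute <- factor(df$attribute, levels = rev(.attribute_ids()))
  df$grade <- factor(df$grade, levels = rev(c("A", "B", "C", "D")))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$attribute, x = .data$pct,
                                   fill = .data$grade)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "% of documented attributes", y = NULL,
                  fill = "Grade") +
    ggplot2::theme_minimal()
}

#' Scatter plot of two raters' overall scores
#'
#' The visual companion to [rih_correlation()]: each point is one
#' innovation scored by both raters, with the identity line for reference.
#'
#' @param x,y Numeric score vectors for raters 1 and 2.
#' @return A ggplot object.
#' @export
plot_rater_scores <- function(x, y) {
  df <- tibble(rater_1 = x, rater_2 = y)
  ggplot2::ggplot(df, ggplot2::aes(.data$rater_1, .data$rater_2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(1, 5), ylim = c(1, 5)) +
    ggplot2::labs(x = "Overall score, rater 1",
                  y = "Overall score, rater 2") +
    ggplot2::theme_minimal()
}
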