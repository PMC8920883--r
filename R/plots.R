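#' Funnel plot of a subgroup screen
#'
#' Subgroup size against the truncated statistic, with the overall estimate
#' as a horizontal reference line. Odds-ratio screens use a log y scale.
#'
#' @param result A `screen_result`.
#' @param outcome One screened outcome.
#' @return A `ggplot` object.
#' @export
funnel_plot <- function(result, outcome) {
  fd <- funnel_data(result, outcome)
  ref <- attr(fd, "reference")
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$n, y = .data$display,
                                        alpha = factor(.data$depth))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = ref, colour = "blue") +
    ggplot2::scale_alpha_manual(values = c(`1` = 0.9, `2` = 0.35,
                                           `3` = 0.2), guide = "none") +
    ggplot2::labs(x = "subgroup size", y = result$config$statistic,
                  title = paste0("Subgroup screen: ", outcome)) +
    ggplot2::theme_minimal()
  if (result$config$statistic == "odds_ratio") p <- p + ggplot2::scale_y_log10()
  p
}

#' Compare two outcomes across subgroups (bubble plot)
#'
#' @param result A `screen_result`.
#' @param outcome_x,outcome_y Two screened outcomes.
#' @return A `ggplot` object.
#' @export
compare_plot <- function(result, outcome_x, outcome_y) {
  cd <- compare_outcomes(result, outcome_x, outcome_y)
  ref <- attr(cd, "reference")
  ggplot2::ggplot(cd[!cd$missing_either, ],
                  ggplot2::aes(x = .data$display_x, y = .data$display_y,
                               size = .data$n_x)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_vline(xintercept = ref[["x"]], colour = "blue") +
    ggplot2::geom_hline(yintercept = ref[["y"]], colour = "blue") +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = outcome_x, y = outcome_y) +
    ggplot2::theme_minimal()
}

#' Interaction (trend) line plot for an ordered factor
#'
#' @param result A `screen_result`.
#' @param factor An ordered catalogue factor.
#' @param outcome One screened outcome.
#' @return A `ggplot` object.
#' @export
trend_plot <- function(result, factor, outcome) {
  tr <- interaction_trend(result, factor, outcome)
  df <- data.frame(level = base::factor(tr$levels, levels = tr$levels),
                   estimate = tr$estimates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$estimate,
                                   group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = factor, y = result$config$statistic,
                  title = paste0(factor, " / ", outcome,
                                 " (", tr$direction, ")")) +
    ggplot2::theme_minimal()
}

#' VIMP and minimal-depth bar chart
#'
#' Horizontal bars of signed permutation importance (blue positive, red
#' negative) ordered by importance, with the minimal-depth selection
#' threshold annotated in the subtitle.
#'
#' @param ffit A `forest_fit`.
#' @return A `ggplot` object.
#' @export
importance_plot <- function(ffit) {
  tab <- importance_table(ffit)
  tab$factor <- base::factor(tab$factor, levels = rev(tab$factor))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$vimp, y = .data$factor,
                                    fill = .data$vimp >= 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "permutation importance (VIMP)", y = NULL,
                  subtitle = sprintf(
                    "minimal-depth threshold %.2f; OOB error %.3f",
                    attr(tab, "min_depth_threshold"), ffit$oob_error)) +
    ggplot2::theme_minimal()
}
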