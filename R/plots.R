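# ggplot2 views of the result tables. All plotting works from the tidy
# tibbles the analysis functions return, so the CSV artifacts and the plots
# always show the same numbers.

#' Yearly report counts as a bar chart
#'
#' @param yearly A [yearly_counts()] tibble.
#' @return A ggplot object.
#' @export
plot_yearly_counts <- function(yearly) {
  ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$n,
                                       fill = .data$peak)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "FDA receipt year", y = "Reports",
                  title = "Reports per year (peak year highlighted)") +
    ggplot2::theme_minimal()
}

#' Binned time-to-onset distribution
#'
#' @param x A `pv_onset_summary`.
#' @return A ggplot object.
#' @export
plot_onset_bins <- function(x) {
  stopifnot(inherits(x, "pv_onset_summary"))
  ggplot2::ggplot(x$bins, ggplot2::aes(x = .data$bin, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "Days from therapy start to event", y = "Share of onsets",
                  title = sprintf("Time to onset (n = %d, median %g d)",
                                  x$n, x$median)) +
    ggplot2::theme_minimal()
}

#' Cumulative onset incidence curve
#'
#' @param curve A [cumulative_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_onset_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$day, y = .data$cum_prop)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days since therapy start",
                  y = "Cumulative proportion of events",
                  title = "Cumulative onset of adverse events") +
    ggplot2::theme_minimal()
}

#' Forest-style view of disproportionality signals
#'
#' Shows the EBGM (observed/expected) point with its 95% interval for the
#' strongest terms; significant signals are highlighted.
#'
#' @param signals A [disproportionality()] tibble.
#' @param top Number of terms (by case count) to show.
#' @return A ggplot object.
#' @export
plot_signals <- function(signals, top = 20) {
  df <- signals %>%
    filter(!is.na(.data$ebgm)) %>%
    arrange(desc(.data$a)) %>%
    head(top) %>%
    mutate(term = stats::reorder(.data$term, .data$ebgm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ebgm, y = .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ebgm_lower,
                                         xmax = .data$ebgm_upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Observed/expected reporting ratio (95% CI)", y = NULL,
                  colour = "Significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_onset_bins
#' @param object A `pv_onset_summary`.
#' @param ... Unused.
#' @export
autoplot.pv_onset_summary <- function(object, ...) plot_onset_bins(object)
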