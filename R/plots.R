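#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a substitution spectrum
#'
#' One bar per substitution type, events per million covered bases on the
#' y axis; multiple conditions are shown as grouped bars.
#'
#' @param spec Spectrum tibble from [spectrum()] (rows from several
#'   conditions may be bound together).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spec) {
  ggplot2::ggplot(spec,
                  ggplot2::aes(x = .data$type, y = .data$per_million,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "substitution type",
                  y = "events per million covered bases",
                  fill = "condition") +
    ggplot2::theme_minimal()
}

#' Histogram of edited sites per clone
#'
#' @param hist Tibble from [edits_per_clone()], or several bound together
#'   with an extra grouping column named `sample`.
#' @return A ggplot object.
#' @export
plot_edits_per_clone <- function(hist) {
  p <- ggplot2::ggplot(hist,
                       ggplot2::aes(x = factor(.data$n_edited),
                                    y = 100 * .data$fraction))
  if ("sample" %in% names(hist)) {
    p <- p + ggplot2::aes(fill = .data$sample) +
      ggplot2::geom_col(position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = "edited sites per cDNA clone", y = "% of clones") +
    ggplot2::theme_minimal()
}

#' Boxplot of expression ratios by editing group
#'
#' @param summary Tibble from [group_ratio_summary()].
#' @return A ggplot object drawing the quartile boxes.
#' @export
plot_group_ratios <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$group,
                                          levels = c("any", "specific", "aa")))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                           width = 0.4) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           width = 0.6, fill = "grey85") +
    ggplot2::labs(x = "editing group", y = "expression ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn independence_fit Observed vs expected edits-per-clone bars.
#' @param object An `indep_fit` object.
#' @param ... Unused.
#' @export
autoplot.indep_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = factor(.data$n_edited),
                               y = .data$fraction,
                               fill = .data$distribution)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "edited sites per clone", y = "fraction of clones",
                  fill = NULL,
                  subtitle = paste0("TV = ", signif(object$statistic, 3),
                                    ", Monte-Carlo p = ",
                                    signif(object$p_value, 3))) +
    ggplot2::theme_minimal()
}

#' @describeIn analyze_editing Spectrum panel per condition.
#' @param object An `editing_analysis`.
#' @param ... Unused.
#' @export
autoplot.editing_analysis <- function(object, ...) {
  plot_spectrum(object$spectra) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::guides(fill = "none")
}
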