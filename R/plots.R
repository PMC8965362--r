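# Diagnostic figures.

#' Plot a chronology with sample depth
#'
#' Growth index line with an optional drought-year marker and the sample
#' depth as a shaded area on a secondary axis.
#'
#' @param chron Chronology tibble (`year`, `index`, `depth`).
#' @param drought_year Optional year to mark.
#' @return A ggplot object.
#' @export
plot_chronology <- function(chron, drought_year = NULL) {
  scale_f <- max(chron$depth) / max(chron$index)
  p <- ggplot2::ggplot(chron, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$depth / scale_f),
                       fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$index)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_continuous(
      "growth index",
      sec.axis = ggplot2::sec_axis(~ . * scale_f, name = "sample depth")
    ) +
    ggplot2::labs(x = "year") +
    ggplot2::theme_minimal()
  if (!is.null(drought_year)) {
    p <- p + ggplot2::geom_vline(xintercept = drought_year,
                                 colour = "firebrick", linetype = "dotted")
  }
  p
}

#' Plot bootstrapped climate-growth correlations
#'
#' Point estimates with bootstrap intervals per month and lag; significant
#' correlations are filled.
#'
#' @param corr Output of [bootstrap_climate_correlation()].
#' @return A ggplot object.
#' @export
plot_climate_correlation <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = factor(.data$month),
                                     y = .data$estimate,
                                     shape = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(~lag) +
    ggplot2::labs(x = "month", y = "correlation with growth index") +
    ggplot2::theme_minimal()
}

#' Plot genetic gains by scenario
#'
#' @param gains Tibble from [compare_scenarios()].
#' @return A ggplot object.
#' @export
plot_gains <- function(gains) {
  ggplot2::ggplot(gains, ggplot2::aes(x = .data$trait, y = .data$gain_pct,
                                      fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "genetic gain (% of phenotypic mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @method autoplot gs_cv
#' @export
autoplot.gs_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$repeat_), y = .data$pa)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$mean_pa, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "repeat", y = "predictive ability",
                  title = sprintf("%s (%s)", object$trait, object$K_kind)) +
    ggplot2::theme_minimal()
}

#' @method autoplot gs_fit
#' @export
autoplot.gs_fit <- function(object, ...) {
  if (is.null(object$ebv)) stop_input("fit carries no breeding values")
  ggplot2::ggplot(object$ebv, ggplot2::aes(x = .data$ebv)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = sprintf("estimated breeding value (%s)", object$trait),
                  y = "trees") +
    ggplot2::theme_minimal()
}
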