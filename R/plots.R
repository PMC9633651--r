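#' Plot methods
#'
#' `autoplot()` methods render the package's result objects with ggplot2:
#' agreement reports as pattern-count bar charts with the count printed
#' under each bar, rescue tables as rescue-frequency-per-ratio-bin bars,
#' ensemble results as a histogram of the winning combined confidence, and
#' [plot_sweep()] shows ensembling gain and similarity against the
#' correlation of a [sweep_correlation()] table.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name softvote-plots
NULL

#' @rdname softvote-plots
#' @export
autoplot.agreement_report <- function(object, ...) {
  dat <- object$patterns
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pattern, y = .data$count)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = "agreement pattern (R right, W wrong)", y = "samples",
      title = sprintf(
        "Learner agreement (S = %.3f ± %.3f)",
        object$similarity$similarity_mean, object$similarity$similarity_se
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname softvote-plots
#' @export
autoplot.rescue_table <- function(object, ...) {
  if (nrow(object$bins) == 0L) {
    return(ggplot2::ggplot() +
      ggplot2::labs(title = "No RWW samples") +
      ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object$bins, ggplot2::aes(x = factor(.data$bin), y = .data$rescue_frequency)) +
    ggplot2::geom_col(fill = "#aa4477") +
    ggplot2::labs(
      x = "second/third-component ratio (quantile bin)",
      y = "rescue frequency",
      title = sprintf("RWW rescue vs confidence-vector shape (%s rule)", object$rule)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname softvote-plots
#' @export
autoplot.ensemble_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$confidence)) +
    ggplot2::geom_histogram(bins = 30, fill = "#44aa77") +
    ggplot2::labs(
      x = "winning combined confidence", y = "samples",
      title = sprintf("%s ensemble", object$rule)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname softvote-plots
#' @param sweep A tibble from [sweep_correlation()].
#' @export
plot_sweep <- function(sweep, ...) {
  dat <- tidyr::pivot_longer(
    sweep[, c("rho", "similarity", "gain_arithmetic", "gain_geometric")],
    -"rho",
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rho, y = .data$value, colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(rho~"(shared logit variance)"), y = NULL,
      title = "Ensembling gain shrinks as learner similarity grows"
    ) +
    ggplot2::theme_minimal()
}
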