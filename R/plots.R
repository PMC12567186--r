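# ggplot2 quick-look graphics for spectra, fits and relaxation maps.

#' Plot isothermal spectra
#'
#' Log-log plot of the chosen quantity versus frequency, coloured by
#' temperature.
#'
#' @param x A `bds_spectra` tibble.
#' @param quantity `"tan_delta"`, `"eps_imag"` or `"eps_real"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_spectra <- function(x, quantity = c("tan_delta", "eps_imag", "eps_real"),
                         ...) {
  quantity <- match.arg(quantity)
  x <- as_bds_spectra(x)
  x$temperature_C <- celsius(x$temperature_K)
  ggplot2::ggplot(x, ggplot2::aes(
    x = .data$frequency_Hz, y = .data[[quantity]],
    colour = .data$temperature_C, group = .data$temperature_C
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = quantity,
                  colour = "T (°C)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bds_spectra <- function(object, ...) plot_spectra(object, ...)

#' Plot a relaxation map
#'
#' log10 relaxation frequency versus 1000/T, one colour per process;
#' Arrhenius-pinned entries are drawn hollow.  The dashed line marks the
#' dielectric glass-transition convention log10 f0 = -2.8.
#'
#' @param x A `relaxation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_relaxation_map <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(
    x = .data$inv1000_over_T, y = .data$log10_f0,
    colour = .data$process_label, shape = .data$provenance
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -2.8, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_shape_manual(
      values = c(fitted = 16, `fixed:arrhenius` = 1)) +
    ggplot2::labs(x = "1000 / T (1/K)", y = "log10 f0 (Hz)",
                  colour = "process", shape = "provenance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.relaxation_map <- function(object, ...) plot_relaxation_map(object, ...)

#' Plot one isotherm fit over its data
#'
#' @param x An `isotherm_fit`.
#' @param spectrum The fitted single-temperature `bds_spectra` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_isotherm_fit <- function(x, spectrum, ...) {
  spectrum <- as_bds_spectra(spectrum)
  f <- spectrum$frequency_Hz
  pred <- model_spectrum(x$model, f)
  ycol <- if (x$representation == "tan_delta") "tan_delta" else "eps_imag"
  ggplot2::ggplot() +
    ggplot2::geom_point(ggplot2::aes(x = f, y = spectrum[[ycol]]),
                        size = 0.8, colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(x = f, y = pred[[ycol]]),
                       colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = ycol,
                  title = sprintf("T = %.1f °C (%s fit)",
                                  celsius(x$temperature_K),
                                  x$representation)) +
    ggplot2::theme_minimal()
}
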