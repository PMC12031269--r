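#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line facet_wrap
#'   scale_x_log10 labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a conductivity sweep
#'
#' Real and negative-imaginary impedance changes against conductivity, one
#' panel per frequency, on a log conductivity axis.
#'
#' @param sweep A sweep tibble.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  sweep <- validate_sweep(sweep)
  long <- tidyr::pivot_longer(sweep, c("re_dz_ohm", "neg_im_dz_ohm"),
                              names_to = "channel", values_to = "dz_ohm")
  ggplot(long, aes(x = .data$kappa_s_per_m, y = .data$dz_ohm,
                   colour = .data$channel)) +
    geom_point() +
    geom_line(alpha = 0.5) +
    scale_x_log10() +
    facet_wrap(~freq_hz, scales = "free_y",
               labeller = ggplot2::label_both) +
    labs(x = "conductivity (S/m)", y = "impedance change (ohm)",
         colour = NULL) +
    theme_minimal()
}

#' @describeIn fit_circuit Data and fitted model curves per frequency.
#' @param object An `ncis_circuit_fit`.
#' @param ... Unused.
#' @export
autoplot.ncis_circuit_fit <- function(object, ...) {
  d <- object$data
  obs <- tidyr::pivot_longer(d[c("freq_hz", "kappa_s_per_m",
                                 "re_dz_ohm", "neg_im_dz_ohm")],
                             c("re_dz_ohm", "neg_im_dz_ohm"),
                             names_to = "channel", values_to = "dz_ohm")
  fitcols <- c(re_dz_ohm = "fitted_re_dz_ohm", neg_im_dz_ohm = "fitted_neg_im_dz_ohm")
  fit <- tidyr::pivot_longer(d[c("freq_hz", "kappa_s_per_m",
                                 "fitted_re_dz_ohm", "fitted_neg_im_dz_ohm")],
                             dplyr::all_of(unname(fitcols)),
                             names_to = "channel", values_to = "dz_ohm")
  fit$channel <- names(fitcols)[match(fit$channel, fitcols)]
  ggplot(obs, aes(x = .data$kappa_s_per_m, y = .data$dz_ohm,
                  colour = .data$channel)) +
    geom_point() +
    geom_line(data = fit, linetype = 2) +
    scale_x_log10() +
    facet_wrap(~freq_hz, scales = "free_y", labeller = ggplot2::label_both) +
    labs(x = "conductivity (S/m)", y = "impedance change (ohm)",
         colour = NULL,
         title = sprintf("Parallel-RC calibration: C1 = %.3g pF",
                         object$params$c1 * 1e12)) +
    theme_minimal()
}

#' @describeIn fit_sigmoid Data with the fitted sigmoid overlaid.
#' @param object An `ncis_sigmoid_fit`.
#' @param ... Unused.
#' @export
autoplot.ncis_sigmoid_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time_h, y = .data$value)) +
    geom_point(alpha = 0.6) +
    geom_line(aes(y = .data$fitted), colour = "black", linetype = 2) +
    labs(x = "time (h)", y = "channel value",
         title = sprintf("Sigmoid fit: Ua = %.3g, tau = %.3g h, t0 = %.3g h",
                         object$params$ua, object$params$tau, object$params$t0)) +
    theme_minimal()
}

#' @describeIn compare_experiment Normalised channels against time, with
#'   falling channels inverted as flagged.
#' @param object An `ncis_comparison`.
#' @param ... Unused.
#' @export
autoplot.ncis_comparison <- function(object, ...) {
  exp <- object$experiment
  long <- imap(exp$curves, function(curve, ch) {
    info <- exp$channel_info[exp$channel_info$channel == ch, ]
    normalize_curve(curve, invert = isTRUE(info$invert[1])) |>
      mutate(channel = ch)
  }) |> bind_rows()
  ggplot(long, aes(x = .data$time_h, y = .data$value, colour = .data$channel)) +
    geom_point(size = 0.8, alpha = 0.7) +
    labs(x = "time (h)", y = "normalised response", colour = NULL,
         title = sprintf("Growth channels vs %s", object$reference)) +
    theme_minimal()
}
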