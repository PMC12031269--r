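#' Generate a synthetic conductivity sweep
#'
#' Evaluates the parallel-RC forward model on a frequency-by-conductivity grid
#' and applies per-channel multiplicative Gaussian noise: each point is
#' multiplied by `1 + rel_sd * z` with `z ~ N(0, 1)`, so the stated percentage
#' standard deviations scale sensibly across the six-plus decades of
#' conductivity a sweep can span. Zero noise returns the exact forward model;
#' nonzero noise requires the seed carried by the [noise_spec()].
#'
#' @param params A [circuit_params()] object.
#' @param freqs Frequencies in Hz (non-empty, > 0).
#' @param kappas Conductivities in S/m (non-empty, > 0).
#' @param noise A [noise_spec()].
#' @param baseline_label Name of the baseline solution recorded with the
#'   sweep (default `"synthetic"`).
#' @return A sweep tibble with columns `freq_hz`, `kappa_s_per_m`,
#'   `re_dz_ohm`, `neg_im_dz_ohm` and attributes `baseline_label`, `eps_r`,
#'   `kappa_b`.
#' @examples
#' p <- circuit_params(c1 = 6e-12, kappa_b = 5.5e-6)
#' gen_sweep(p, freqs = c(1e4, 5e4), kappas = 10^seq(-5, 0),
#'           noise = noise_spec(0.007, 4e-4, seed = 1))
#' @export
gen_sweep <- function(params, freqs, kappas, noise = noise_spec(),
                      baseline_label = "synthetic") {
  if (!inherits(params, "circuit_params")) {
    ncis_abort("`params` must be a circuit_params object.", "ncis_invalid_input")
  }
  if (!inherits(noise, "noise_spec")) {
    ncis_abort("`noise` must be a noise_spec object.", "ncis_invalid_input")
  }
  if (length(freqs) == 0 || length(kappas) == 0) {
    ncis_abort("`freqs` and `kappas` must be non-empty.", "ncis_invalid_input")
  }
  stopifnot_positive(freqs, "freqs")
  stopifnot_positive(kappas, "kappas")

  sweep <- model_sweep_values(params, freqs, kappas)
  if (noise$rel_sd_re > 0 || noise$rel_sd_im > 0) {
    sweep <- withr::with_seed(noise$seed, {
      n <- nrow(sweep)
      mutate(sweep,
             re_dz_ohm = .data$re_dz_ohm * (1 + noise$rel_sd_re * rnorm(n)),
             neg_im_dz_ohm = .data$neg_im_dz_ohm * (1 + noise$rel_sd_im * rnorm(n)))
    })
  }
  attr(sweep, "baseline_label") <- baseline_label
  attr(sweep, "eps_r") <- params$eps_r
  attr(sweep, "kappa_b") <- params$kappa_b
  sweep
}

#' Generate a synthetic multi-channel growth experiment
#'
#' Builds an [ncis_experiment()] from per-channel growth models. Channels whose
#' role is `"od"` are subsampled at the OD sampling interval (optionally with
#' uniform timing jitter, since optical samples are drawn by hand at only
#' roughly regular intervals); all other channels are recorded on the full
#' time grid, emulating the continuously logging impedance and reflection
#' channels. Noise is multiplicative Gaussian with the real-channel relative
#' standard deviation of `noise` applied to every channel.
#'
#' @param channel_models Named list of [sigmoid_params()] or
#'   [unified_params()] objects, one per channel.
#' @param t_grid Strictly increasing time grid in hours.
#' @param od_interval OD sampling interval in hours (default 0.5; the
#'   reference workflow samples every 0.5-1 h).
#' @param noise A [noise_spec()]; its `rel_sd_re` is used for all channels.
#' @param channel_info Optional channel metadata tibble (see
#'   [ncis_experiment()]); defaults assign role `"od"` to `reference`, role
#'   `"or"` with `invert = TRUE` to channels whose model amplitude is negative
#'   and which are flagged in `or_channels`, and `"impedance"` otherwise.
#' @param or_channels Channel labels to flag as optical-reflection channels.
#' @param reference Reference channel label (default `"od_600"`).
#' @param od_jitter Fraction of `od_interval` by which OD sampling times
#'   jitter uniformly (default 0.1; requires a seed when nonzero).
#' @param metadata Free-form metadata list.
#' @return An [ncis_experiment()].
#' @examples
#' models <- list(
#'   od_600 = sigmoid_params(1.5, 0.5, 7.2),
#'   re_dz_15khz = sigmoid_params(5000, 0.5, 5.6))
#' gen_growth_experiment(models, t_grid = seq(0, 14, 0.05), od_jitter = 0)
#' @export
gen_growth_experiment <- function(channel_models, t_grid, od_interval = 0.5,
                                  noise = noise_spec(), channel_info = NULL,
                                  or_channels = character(),
                                  reference = "od_600", od_jitter = 0.1,
                                  metadata = list()) {
  if (!is.list(channel_models) || length(channel_models) == 0 ||
      is.null(names(channel_models))) {
    ncis_abort("`channel_models` must be a non-empty named list of model parameter objects.",
               "ncis_invalid_input")
  }
  if (is.unsorted(t_grid, strictly = TRUE)) {
    ncis_abort("`t_grid` must be strictly increasing.", "ncis_invalid_input")
  }
  stopifnot_positive(od_interval, "od_interval")
  if (!inherits(noise, "noise_spec")) {
    ncis_abort("`noise` must be a noise_spec object.", "ncis_invalid_input")
  }
  needs_rng <- noise$rel_sd_re > 0 || od_jitter > 0
  if (needs_rng && is.null(noise$seed)) {
    ncis_abort("A seeded noise_spec is required for nonzero noise or OD-time jitter.",
               "ncis_invalid_input")
  }

  if (is.null(channel_info)) {
    channel_info <- tibble(
      channel = names(channel_models),
      units = NA_character_,
      invert = names(channel_models) %in% or_channels,
      role = dplyr::case_when(
        names(channel_models) == reference ~ "od",
        names(channel_models) %in% or_channels ~ "or",
        TRUE ~ "impedance"
      )
    )
  }

  eval_model <- function(model, t) {
    if (inherits(model, "sigmoid_params")) {
      sigmoid_value(model, t)
    } else if (inherits(model, "unified_params")) {
      unified_growth(model, t)
    } else {
      ncis_abort("Channel models must be sigmoid_params or unified_params.",
                 "ncis_invalid_input")
    }
  }

  build <- function() {
    imap(channel_models, function(model, ch) {
      role <- channel_info$role[channel_info$channel == ch][1]
      if (identical(role, "od")) {
        times <- seq(min(t_grid), max(t_grid), by = od_interval)
        if (od_jitter > 0) {
          jit <- runif(length(times), -od_jitter, od_jitter) * od_interval
          times <- sort(pmin(pmax(times + jit, min(t_grid)), max(t_grid)))
          times <- unique(times)   # clamping can collide at the window edges
        }
      } else {
        times <- t_grid
      }
      values <- eval_model(model, times)
      if (noise$rel_sd_re > 0) {
        values <- values * (1 + noise$rel_sd_re * rnorm(length(values)))
      }
      tibble(time_h = times, value = values)
    })
  }

  curves <- if (needs_rng) withr::with_seed(noise$seed, build()) else build()
  ncis_experiment(curves, channel_info = channel_info,
                  tsample_h = od_interval, reference = reference,
                  metadata = metadata)
}

#' Generate a temperature trace and its conductivity factor
#'
#' Draws independent Gaussian temperatures around the setpoint and converts
#' them to a multiplicative conductivity factor
#' `1 + kappa_coeff * (T - mean_c)`. At the stabilities achieved by the
#' reference instruments (a few millikelvin) and a 2%/degC coefficient, the
#' factor deviates from one by well under 0.1%, which is why growth data are
#' not temperature-corrected.
#'
#' @param spec A [temperature_spec()].
#' @param t_grid Time grid in hours.
#' @return A tibble with columns `time_h`, `temp_c`, `kappa_factor`.
#' @examples
#' gen_temperature_trace(temperature_spec(37, 0.011, seed = 1), seq(0, 10, 0.1))
#' @export
gen_temperature_trace <- function(spec, t_grid) {
  if (!inherits(spec, "temperature_spec")) {
    ncis_abort("`spec` must be a temperature_spec object.", "ncis_invalid_input")
  }
  stopifnot_finite(t_grid, "t_grid")
  draw <- function() spec$mean_c + spec$sd_c * rnorm(length(t_grid))
  temps <- if (spec$sd_c > 0) withr::with_seed(spec$seed, draw()) else draw()
  tibble(
    time_h = t_grid,
    temp_c = temps,
    kappa_factor = 1 + spec$kappa_coeff * (temps - spec$mean_c)
  )
}
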