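#' Complex impedance of the parallel-RC conductivity cell
#'
#' Forward model of the non-contact cell: the solution behaves as a resistor
#' `R = Kcell / kappa` in parallel with the coupling capacitance `C1`, giving
#' `Z = R / (1 + i * omega * R * C1)`. The cell constant and coupling
#' capacitance are linked by `C1 = eps_r * eps0 / Kcell`, so either a
#' [circuit_params()] or a [cell_geometry()] object determines the model.
#'
#' @param params A [circuit_params()] or [cell_geometry()] object.
#' @param kappa Solution conductivity in S/m (> 0); vectorised.
#' @param freq Frequency in Hz (> 0); vectorised.
#' @param eps_r Relative permittivity, used only when `params` is a
#'   [cell_geometry()] (defaults to 78).
#' @return A complex vector of impedances in ohms, with positive real part and
#'   non-positive imaginary part.
#' @examples
#' # DC limit: Z -> Kcell / kappa
#' impedance_rc(cell_geometry(10.6), kappa = 1.49, freq = 1e-3)
#' @export
impedance_rc <- function(params, kappa, freq, eps_r = 78) {
  stopifnot_positive(kappa, "kappa")
  stopifnot_positive(freq, "freq")
  if (inherits(params, "circuit_params")) {
    c1 <- params$c1
    kcell <- cell_constant_from_c1(c1, params$eps_r)
  } else if (inherits(params, "cell_geometry")) {
    kcell <- params$kcell
    c1 <- c1_from_cell_constant(kcell, eps_r)
  } else {
    ncis_abort("`params` must be a circuit_params or cell_geometry object.",
               "ncis_invalid_input")
  }
  r <- kcell / kappa
  omega <- 2 * pi * freq
  r / (1 + 1i * omega * r * c1)
}

#' Real part of the impedance change between a solution and the baseline
#'
#' Closed form for `Re(dZ) = Re Z(kappa0) - Re Z(kappa_b)` of the parallel-RC
#' cell:
#' `(eps0 * eps_r / C1) * (kappa0 / (kappa0^2 + a^2) - kappa_b / (kappa_b^2 + a^2))`
#' with `a = omega * eps_r * eps0`. Vectorised over `kappa0` and `freq`.
#'
#' @param params A [circuit_params()] object (supplies `c1`, `eps_r`,
#'   `kappa_b`).
#' @param kappa0 Conductivity of the measured solution in S/m (> 0).
#' @param freq Frequency in Hz (> 0).
#' @return Impedance change in ohms.
#' @examples
#' p <- circuit_params(c1 = 6e-12, kappa_b = 5.5e-6)
#' delta_z_real(p, kappa0 = 1e-4, freq = 1e4)
#' @export
delta_z_real <- function(params, kappa0, freq) {
  if (!inherits(params, "circuit_params")) {
    ncis_abort("`params` must be a circuit_params object.", "ncis_invalid_input")
  }
  stopifnot_positive(kappa0, "kappa0")
  stopifnot_positive(freq, "freq")
  a <- 2 * pi * freq * params$eps_r * eps0
  scale <- eps0 * params$eps_r / params$c1
  term <- function(k) k / (k^2 + a^2)
  scale * (term(kappa0) - term(params$kappa_b))
}

#' Negative imaginary part of the impedance change
#'
#' Closed form for `-Im(dZ)` of the parallel-RC cell:
#' `omega * (eps_r * eps0)^2 / C1 * (1 / (kappa0^2 + a^2) - 1 / (kappa_b^2 + a^2))`
#' with `a = omega * eps_r * eps0`. The sign convention matches the usual
#' Nyquist presentation where `-Im Z` is plotted upward.
#'
#' @inheritParams delta_z_real
#' @return Impedance change in ohms (strictly decreasing in `kappa0`).
#' @examples
#' p <- circuit_params(c1 = 6e-12, kappa_b = 5.5e-6)
#' delta_z_neg_imag(p, kappa0 = 1e-4, freq = 1e4)
#' @export
delta_z_neg_imag <- function(params, kappa0, freq) {
  if (!inherits(params, "circuit_params")) {
    ncis_abort("`params` must be a circuit_params object.", "ncis_invalid_input")
  }
  stopifnot_positive(kappa0, "kappa0")
  stopifnot_positive(freq, "freq")
  omega <- 2 * pi * freq
  a <- omega * params$eps_r * eps0
  scale <- omega * (params$eps_r * eps0)^2 / params$c1
  term <- function(k) 1 / (k^2 + a^2)
  scale * (term(kappa0) - term(params$kappa_b))
}

#' Conductivity of maximal real-impedance response
#'
#' The single-solution real term of the cell model peaks at
#' `kappa_0d = 2 * pi * f * eps_r * eps0`, which depends only on frequency and
#' solution permittivity. At 10 kHz and `eps_r = 78` this is about 4.3e-5 S/m;
#' at 300 MHz about 1.3 S/m.
#'
#' @param freq Frequency in Hz (> 0); vectorised.
#' @param eps_r Relative permittivity (> 0), default 78.
#' @return Conductivity in S/m.
#' @examples
#' peak_conductivity(1e4)
#' peak_conductivity(3e8)
#' @export
peak_conductivity <- function(freq, eps_r = 78) {
  stopifnot_positive(freq, "freq")
  stopifnot_positive(eps_r, "eps_r")
  2 * pi * freq * eps_r * eps0
}

#' High-sensitivity conductivity band at a frequency
#'
#' The measurable dynamic range spans about one order of magnitude either side
#' of the peak conductivity `kappa_0d`, so the band is
#' `(kappa_0d / 10, 10 * kappa_0d)` — two decades with `kappa_0d` at the
#' geometric centre.
#'
#' @inheritParams peak_conductivity
#' @return A tibble with columns `freq_hz`, `kappa_low`, `kappa_high` (S/m).
#' @examples
#' sensitivity_band(c(1e4, 3e8))
#' @export
sensitivity_band <- function(freq, eps_r = 78) {
  kd <- peak_conductivity(freq, eps_r)
  tibble(freq_hz = freq, kappa_low = kd / 10, kappa_high = 10 * kd)
}

#' Convert between coupling capacitance and cell constant
#'
#' The coupling capacitance and cell constant of the parallel-RC cell are
#' linked by `C1 = eps_r * eps0 / Kcell`, which makes the RC time constant
#' `tau = eps_r * eps0 / kappa` independent of geometry.
#'
#' @param c1 Coupling capacitance in farads (> 0).
#' @param kcell Cell constant in 1/m (> 0).
#' @param eps_r Relative permittivity (> 0), default 78.
#' @return `cell_constant_from_c1()` returns a cell constant in 1/m;
#'   `c1_from_cell_constant()` returns a capacitance in farads.
#' @examples
#' cell_constant_from_c1(2e-12)   # ~345 1/m
#' @export
cell_constant_from_c1 <- function(c1, eps_r = 78) {
  stopifnot_positive(c1, "c1")
  stopifnot_positive(eps_r, "eps_r")
  eps_r * eps0 / c1
}

#' @rdname cell_constant_from_c1
#' @export
c1_from_cell_constant <- function(kcell, eps_r = 78) {
  stopifnot_positive(kcell, "kcell")
  stopifnot_positive(eps_r, "eps_r")
  eps_r * eps0 / kcell
}

#' Solution resistance from the cell constant
#'
#' `R = Kcell / kappa` for a cell with constant `Kcell` filled with a solution
#' of conductivity `kappa`.
#'
#' @param geom A [cell_geometry()] object, or a bare cell constant in 1/m.
#' @param kappa Conductivity in S/m (> 0); vectorised.
#' @return Resistance in ohms.
#' @examples
#' solution_resistance(cell_geometry(10.6), 1.75)  # ~6.06 ohm
#' @export
solution_resistance <- function(geom, kappa) {
  kcell <- if (inherits(geom, "cell_geometry")) geom$kcell else geom
  stopifnot_positive(kcell, "kcell")
  if (!is.numeric(kappa) || any(!is.finite(kappa))) {
    ncis_abort("`kappa` must be finite and numeric.", "ncis_invalid_input")
  }
  if (any(kappa == 0)) {
    ncis_abort("`kappa` must be nonzero: resistance Kcell / kappa is undefined at kappa = 0.",
               "ncis_invalid_input")
  }
  if (any(kappa < 0)) {
    ncis_abort("`kappa` must be strictly positive.", "ncis_invalid_input")
  }
  kcell / kappa
}

# model sweep table on a (freq x kappa) grid; internal workhorse shared by the
# generator and the calibration fit
model_sweep_values <- function(params, freqs, kappas) {
  grid <- tidyr::expand_grid(freq_hz = freqs, kappa_s_per_m = kappas)
  grid |>
    mutate(
      re_dz_ohm = delta_z_real(params, .data$kappa_s_per_m, .data$freq_hz),
      neg_im_dz_ohm = delta_z_neg_imag(params, .data$kappa_s_per_m, .data$freq_hz)
    )
}

#' Calibrate the coupling capacitance from a conductivity sweep
#'
#' Fits the single adjustable parameter `C1` of the parallel-RC cell model to a
#' conductivity sweep by joint weighted least squares over the real and
#' negative-imaginary impedance-change channels. Both model channels are
#' proportional to `1 / C1`, so the weighted problem is linear in `1 / C1` and
#' is solved in closed form; each channel is weighted by the inverse square of
#' its maximum absolute observed value so the small imaginary-channel values
#' are not drowned by the real part.
#'
#' @param sweep A sweep tibble with columns `freq_hz`, `kappa_s_per_m`,
#'   `re_dz_ohm`, `neg_im_dz_ohm` (as produced by [gen_sweep()] or
#'   [read_sweep()]).
#' @param eps_r Relative permittivity of the solutions (default 78, or the
#'   sweep's `eps_r` attribute when present).
#' @param kappa_b Baseline-solution conductivity in S/m (default from the
#'   sweep's `kappa_b` attribute, else 0).
#' @return An object of class `ncis_circuit_fit` with elements `params`
#'   (a [circuit_params()]), `kcell`, `diagnostics` (residual norm, per-channel
#'   relative RMS, standard error of `c1`) and the data with fitted values.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' p <- circuit_params(c1 = 6e-12, kappa_b = 5.5e-6)
#' sw <- gen_sweep(p, freqs = c(1e4, 5e4), kappas = 10^seq(-5, 0, 1))
#' fit_circuit(sw)
#' @export
fit_circuit <- function(sweep, eps_r = NULL, kappa_b = NULL) {
  sweep <- validate_sweep(sweep)
  if (is.null(eps_r)) eps_r <- attr(sweep, "eps_r") %||% 78
  if (is.null(kappa_b)) kappa_b <- attr(sweep, "kappa_b") %||% 0
  if (dplyr::n_distinct(sweep$kappa_s_per_m) < 2) {
    ncis_abort("Sweep must contain at least 2 distinct conductivities to calibrate C1.",
               "ncis_insufficient_data")
  }

  # model values at C1 = 1 F; true model is (1/C1) times these
  base <- circuit_params(c1 = 1, eps_r = eps_r, kappa_b = kappa_b)
  m_re <- delta_z_real(base, sweep$kappa_s_per_m, sweep$freq_hz)
  m_im <- delta_z_neg_imag(base, sweep$kappa_s_per_m, sweep$freq_hz)

  y <- c(sweep$re_dz_ohm, sweep$neg_im_dz_ohm)
  m <- c(m_re, m_im)
  channel <- rep(c("re_dz", "neg_im_dz"), each = nrow(sweep))
  scale_re <- max(abs(sweep$re_dz_ohm))
  scale_im <- max(abs(sweep$neg_im_dz_ohm))
  if (scale_re == 0 && scale_im == 0) {
    ncis_abort("Sweep is identically zero (single solution equal to the baseline?); cannot calibrate.",
               "ncis_insufficient_data")
  }
  w <- ifelse(channel == "re_dz",
              if (scale_re > 0) 1 / scale_re^2 else 0,
              if (scale_im > 0) 1 / scale_im^2 else 0)

  denom <- sum(w * m^2)
  if (denom == 0) {
    ncis_abort("Model values vanish on this sweep; C1 is unidentifiable.",
               "ncis_fit_failure")
  }
  b <- sum(w * y * m) / denom    # b = 1/C1
  if (!is.finite(b) || b <= 0) {
    ncis_abort("Calibration produced a non-positive capacitance; check sweep signs and baseline.",
               "ncis_fit_failure")
  }
  c1_hat <- 1 / b

  fitted <- m * b
  res <- y - fitted
  dof <- length(y) - 1L
  sigma2 <- sum(w * res^2) / max(dof, 1L)
  se_b <- sqrt(sigma2 / denom)
  se_c1 <- se_b / b^2   # delta method for C1 = 1/b

  rel_rms <- tibble(
    channel = c("re_dz", "neg_im_dz"),
    rel_rms = c(
      sqrt(mean((res[channel == "re_dz"])^2)) / max(scale_re, .Machine$double.eps),
      sqrt(mean((res[channel == "neg_im_dz"])^2)) / max(scale_im, .Machine$double.eps)
    )
  )

  data <- sweep |>
    mutate(fitted_re_dz_ohm = m_re * b, fitted_neg_im_dz_ohm = m_im * b)

  structure(
    list(
      params = circuit_params(c1 = c1_hat, eps_r = eps_r, kappa_b = kappa_b),
      kcell = cell_constant_from_c1(c1_hat, eps_r),
      diagnostics = list(
        residual_norm = sqrt(sum(w * res^2)),
        rel_rms = rel_rms,
        se_c1 = se_c1,
        n = nrow(sweep)
      ),
      data = data
    ),
    class = "ncis_circuit_fit"
  )
}

#' @export
print.ncis_circuit_fit <- function(x, ...) {
  cat("Parallel-RC cell calibration\n")
  cat(sprintf("  C1    = %.4g pF (se %.2g pF)\n",
              x$params$c1 * 1e12, x$diagnostics$se_c1 * 1e12))
  cat(sprintf("  Kcell = %.4g 1/m  (eps_r = %g, kappa_b = %.3g S/m)\n",
              x$kcell, x$params$eps_r, x$params$kappa_b))
  cat(sprintf("  n = %d records; weighted residual norm = %.3g\n",
              x$diagnostics$n, x$diagnostics$residual_norm))
  rr <- x$diagnostics$rel_rms
  cat(sprintf("  relative RMS: re_dz %.3g, neg_im_dz %.3g\n",
              rr$rel_rms[rr$channel == "re_dz"],
              rr$rel_rms[rr$channel == "neg_im_dz"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sweep <- function(sweep) {
  required <- c("freq_hz", "kappa_s_per_m", "re_dz_ohm", "neg_im_dz_ohm")
  missing_cols <- setdiff(required, names(sweep))
  if (length(missing_cols) > 0) {
    ncis_abort(sprintf("Sweep is missing column(s): %s.",
                       paste(missing_cols, collapse = ", ")),
               "ncis_invalid_input")
  }
  if (nrow(sweep) == 0) {
    ncis_abort("Sweep contains no records.", "ncis_insufficient_data")
  }
  stopifnot_positive(sweep$freq_hz, "freq_hz")
  stopifnot_positive(sweep$kappa_s_per_m, "kappa_s_per_m")
  if (anyDuplicated(sweep[c("freq_hz", "kappa_s_per_m")]) > 0) {
    ncis_abort("Sweep contains duplicate (freq, kappa) pairs.",
               "ncis_invalid_input")
  }
  as_tibble(sweep)
}
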