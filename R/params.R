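#' Parallel-RC cell model parameters
#'
#' Bundles the coupling capacitance, relative permittivity and baseline
#' conductivity that parameterise the non-contact cell model. The capacitance
#' `c1` is the single adjustable parameter of the model; `kappa_b` is the
#' conductivity of the baseline solution subtracted from every sweep (ultra-pure
#' water in the reference measurements, 5.5e-6 S/m).
#'
#' @param c1 Coupling capacitance in farads (> 0).
#' @param eps_r Relative permittivity of the solution (> 0); defaults to 78,
#'   the value for water.
#' @param kappa_b Baseline-solution conductivity in S/m (>= 0).
#' @return An object of class `circuit_params`.
#' @examples
#' circuit_params(c1 = 6e-12, kappa_b = 5.5e-6)
#' @export
circuit_params <- function(c1, eps_r = 78, kappa_b = 0) {
  stopifnot_positive(c1, "c1")
  stopifnot_positive(eps_r, "eps_r")
  stopifnot_finite(kappa_b, "kappa_b")
  if (kappa_b < 0) ncis_abort("`kappa_b` must be >= 0.", "ncis_invalid_input")
  structure(list(c1 = c1, eps_r = eps_r, kappa_b = kappa_b),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> C1 = %.4g pF, eps_r = %g, kappa_b = %.4g S/m\n",
              x$c1 * 1e12, x$eps_r, x$kappa_b))
  invisible(x)
}

#' Conductivity-cell geometry
#'
#' The cell constant relates solution resistance to conductivity through
#' R = Kcell / kappa.
#'
#' @param kcell Cell constant in 1/m (> 0).
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry(10.6)
#' @export
cell_geometry <- function(kcell) {
  stopifnot_positive(kcell, "kcell")
  structure(list(kcell = kcell), class = "cell_geometry")
}

#' Sigmoidal growth-curve parameters
#'
#' Amplitude, growth time constant and time lag of the logistic growth law
#' `U(t) = Ua / (1 + exp(-(t - t0)/tau))`. The sign of `ua` encodes the
#' direction of change: impedance channels that fall during growth carry a
#' negative amplitude.
#'
#' @param ua Amplitude in channel units (non-zero).
#' @param tau Growth time constant in hours (> 0).
#' @param t0 Time lag in hours.
#' @return An object of class `sigmoid_params`.
#' @examples
#' sigmoid_params(ua = 4550, tau = 0.25, t0 = 6.0)
#' @export
sigmoid_params <- function(ua, tau, t0) {
  stopifnot_finite(ua, "ua")
  if (ua == 0) ncis_abort("`ua` must be non-zero.", "ncis_invalid_input")
  stopifnot_positive(tau, "tau")
  stopifnot_finite(t0, "t0")
  structure(list(ua = ua, tau = tau, t0 = t0), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("<sigmoid_params> Ua = %.4g, tau = %.4g h, t0 = %.4g h\n",
              x$ua, x$tau, x$t0))
  invisible(x)
}

#' Unified two-region growth-model parameters
#'
#' Parameters of the reduced unified growth law combining wall-adherent and
#' bulk bacterial growth: a normalisation `un`, the volume growth time constant
#' `tau_u`, the wall-growth lag `t0w`, the bulk-growth lag `t0b`, and the ratio
#' of the bulk to wall resistivity indices `rho_ratio` (rho_a1 / rho_a2).
#'
#' @param un Normalisation constant (> 0, dimensionless).
#' @param tau_u Volume growth time constant in hours (> 0).
#' @param t0w Wall-growth time lag in hours.
#' @param t0b Bulk-growth time lag in hours.
#' @param rho_ratio Resistivity-index ratio rho_a1 / rho_a2 (> 0).
#' @return An object of class `unified_params`.
#' @examples
#' unified_params(un = 1, tau_u = 1.0, t0w = 5.6, t0b = 7.2, rho_ratio = 3.5)
#' @export
unified_params <- function(un, tau_u, t0w, t0b, rho_ratio) {
  stopifnot_positive(un, "un")
  stopifnot_positive(tau_u, "tau_u")
  stopifnot_finite(t0w, "t0w")
  stopifnot_finite(t0b, "t0b")
  stopifnot_positive(rho_ratio, "rho_ratio")
  structure(list(un = un, tau_u = tau_u, t0w = t0w, t0b = t0b,
                 rho_ratio = rho_ratio),
            class = "unified_params")
}

#' @export
print.unified_params <- function(x, ...) {
  cat(sprintf(
    "<unified_params> Un = %.4g, tau_u = %.4g h, t0w = %.4g h, t0b = %.4g h, rho_a1/rho_a2 = %.4g\n",
    x$un, x$tau_u, x$t0w, x$t0b, x$rho_ratio))
  invisible(x)
}

#' Two-region container geometry
#'
#' Geometry and resistivity indices of the two coaxial growth regions in a
#' cylindrical container: a central bulk rod and a wall-adjacent annulus, in
#' parallel between the top and bottom electrodes.
#'
#' @param r2 Inner container radius in metres (> 0).
#' @param h Electrode-to-electrode height in metres (> 0).
#' @param rho_a1 Bulk resistivity-index amplitude (> 0, arbitrary units).
#' @param rho_a2 Wall-region resistivity index (> 0, same units).
#' @return An object of class `two_region_geometry`.
#' @examples
#' two_region_geometry(r2 = 0.04, h = 0.0823, rho_a1 = 3.5, rho_a2 = 1)
#' @export
two_region_geometry <- function(r2, h, rho_a1, rho_a2) {
  stopifnot_positive(r2, "r2")
  stopifnot_positive(h, "h")
  stopifnot_positive(rho_a1, "rho_a1")
  stopifnot_positive(rho_a2, "rho_a2")
  structure(list(r2 = r2, h = h, rho_a1 = rho_a1, rho_a2 = rho_a2),
            class = "two_region_geometry")
}

#' Multiplicative measurement-noise specification
#'
#' Relative (per-point, multiplicative Gaussian) standard deviations for the
#' real and imaginary impedance channels, plus the seed that makes any nonzero
#' noise reproducible. Reference levels from the instrument characterisation:
#' 0.7% / 0.04% for the lab-bottle sweeps and 3.6% / 0.14% (5 MHz) or
#' 0.7% / 0.06% (30-300 MHz) for the well-plate sweeps.
#'
#' @param rel_sd_re Relative standard deviation of the real part (>= 0).
#' @param rel_sd_im Relative standard deviation of the imaginary part (>= 0).
#' @param seed Integer seed; required whenever either sd is nonzero.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(0.007, 0.0004, seed = 1)
#' noise_spec(0, 0)   # noise-free, no seed needed
#' @export
noise_spec <- function(rel_sd_re = 0, rel_sd_im = rel_sd_re, seed = NULL) {
  stopifnot_finite(rel_sd_re, "rel_sd_re")
  stopifnot_finite(rel_sd_im, "rel_sd_im")
  if (rel_sd_re < 0 || rel_sd_im < 0) {
    ncis_abort("Noise standard deviations must be >= 0.", "ncis_invalid_input")
  }
  if ((rel_sd_re > 0 || rel_sd_im > 0) && is.null(seed)) {
    ncis_abort("A `seed` is required for nonzero noise.", "ncis_invalid_input")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(rel_sd_re = rel_sd_re, rel_sd_im = rel_sd_im, seed = seed),
            class = "noise_spec")
}

#' Temperature-jitter specification
#'
#' Gaussian temperature fluctuations around a setpoint together with the
#' relative conductivity temperature coefficient used to propagate them into
#' the impedance forward model. The default coefficient is 2%/degC, the value
#' reported for KCl solutions and BHI growth medium; the coefficient implied by
#' the reference BHI-medium conductivities (1.49 S/m at 25 degC, 1.75 S/m at 37 degC) is
#' slightly lower, about 1.45%/degC.
#'
#' @param mean_c Setpoint temperature in degC.
#' @param sd_c Temperature standard deviation in degC (>= 0).
#' @param kappa_coeff Relative conductivity change per degC (default 0.02).
#' @param seed Integer seed; required whenever `sd_c > 0`.
#' @return An object of class `temperature_spec`.
#' @examples
#' temperature_spec(37.0, 0.011, seed = 1)
#' @export
temperature_spec <- function(mean_c, sd_c, kappa_coeff = 0.02, seed = NULL) {
  stopifnot_finite(mean_c, "mean_c")
  stopifnot_finite(sd_c, "sd_c")
  if (sd_c < 0) ncis_abort("`sd_c` must be >= 0.", "ncis_invalid_input")
  stopifnot_finite(kappa_coeff, "kappa_coeff")
  if (sd_c > 0 && is.null(seed)) {
    ncis_abort("A `seed` is required for nonzero temperature jitter.",
               "ncis_invalid_input")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(mean_c = mean_c, sd_c = sd_c, kappa_coeff = kappa_coeff,
                 seed = seed),
            class = "temperature_spec")
}
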