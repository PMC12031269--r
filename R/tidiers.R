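#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a parallel-RC calibration
#'
#' @param x An `ncis_circuit_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.ncis_circuit_fit <- function(x, ...) {
  tibble(term = "c1", estimate = x$params$c1, std.error = x$diagnostics$se_c1)
}

#' @rdname tidy.ncis_circuit_fit
#' @return `glance()` returns a one-row tibble of fit diagnostics.
#' @export
glance.ncis_circuit_fit <- function(x, ...) {
  rr <- x$diagnostics$rel_rms
  tibble(
    c1 = x$params$c1,
    kcell = x$kcell,
    eps_r = x$params$eps_r,
    kappa_b = x$params$kappa_b,
    residual_norm = x$diagnostics$residual_norm,
    rel_rms_re = rr$rel_rms[rr$channel == "re_dz"],
    rel_rms_neg_im = rr$rel_rms[rr$channel == "neg_im_dz"],
    nobs = x$diagnostics$n
  )
}

#' Tidy a sigmoidal growth fit
#'
#' @param x An `ncis_sigmoid_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`ua`, `tau`, `t0`).
#' @export
tidy.ncis_sigmoid_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, 3)
  tibble(
    term = c("ua", "tau", "t0"),
    estimate = c(x$params$ua, x$params$tau, x$params$t0),
    std.error = unname(se[c("ua", "tau", "t0")])
  )
}

#' @rdname tidy.ncis_sigmoid_fit
#' @export
glance.ncis_sigmoid_fit <- function(x, ...) {
  tibble(ua = x$params$ua, tau = x$params$tau, t0 = x$params$t0,
         resid_rms = x$resid_rms, nobs = x$n)
}

#' Tidy a unified two-region growth fit
#'
#' @param x An `ncis_unified_fit`.
#' @param ... Unused.
#' @return A tibble with the shared time parameters and the per-curve
#'   resistivity-index ratios.
#' @export
tidy.ncis_unified_fit <- function(x, ...) {
  bind_rows(
    tibble(term = c("tau_u", "t0w", "t0b"), curve = NA_character_,
           estimate = c(x$tau_u, x$t0w, x$t0b)),
    tibble(term = "rho_ratio", curve = x$curves$curve,
           estimate = x$curves$rho_ratio),
    tibble(term = "un", curve = x$curves$curve, estimate = x$curves$un)
  )
}

#' @rdname tidy.ncis_unified_fit
#' @export
glance.ncis_unified_fit <- function(x, ...) {
  tibble(
    tau_u = x$tau_u, t0w = x$t0w, t0b = x$t0b,
    rho_ratio_low = x$curves$rho_ratio[x$curves$curve == "low"],
    rho_ratio_high = x$curves$rho_ratio[x$curves$curve == "high"],
    lag_order_warning = x$diagnostics$lag_order_warning,
    joint_refit = x$diagnostics$joint_refit
  )
}

#' Tidy a channel comparison
#'
#' @param x An `ncis_comparison`.
#' @param ... Unused.
#' @return The per-channel results tibble (sigmoid parameters, delay,
#'   regression statistics).
#' @export
tidy.ncis_comparison <- function(x, ...) {
  x$channels
}

#' @rdname tidy.ncis_comparison
#' @export
glance.ncis_comparison <- function(x, ...) {
  ncis <- x$channels[x$channels$channel != x$reference, ]
  tibble(
    reference = x$reference,
    n_channels = nrow(x$channels),
    od_low = x$od_range[1],
    od_high = x$od_range[2],
    min_r_squared = suppressWarnings(min(ncis$r_squared, na.rm = TRUE)),
    max_abs_tdelay = suppressWarnings(max(abs(ncis$tdelay), na.rm = TRUE))
  )
}
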