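#' Assemble a multi-channel growth experiment
#'
#' Bundles aligned growth channels (impedance at named frequencies, optical
#' density, optical reflection) recorded on one experiment clock, together with
#' per-channel metadata and the OD sampling period.
#'
#' @param curves Either a long tibble with columns `channel`, `time_h`,
#'   `value`, or a named list of per-channel tibbles with columns `time_h`,
#'   `value`.
#' @param channel_info Optional tibble with columns `channel`, `units`,
#'   `invert` (logical: channel falls during growth and is inverted on
#'   normalisation) and `role` (one of `"impedance"`, `"od"`, `"or"`). When
#'   omitted, every channel is treated as an impedance channel except the
#'   reference, which gets role `"od"`; `invert` defaults to `FALSE`.
#'   Inversion is driven by this flag, never by channel-name matching.
#' @param tsample_h OD sampling period in hours (> 0).
#' @param reference Label of the reference channel (default `"od_600"`).
#' @param metadata Free-form named list (species, temperature summary, ...).
#' @return An object of class `ncis_experiment`.
#' @examples
#' tg <- seq(0, 14, 0.1)
#' exp <- ncis_experiment(
#'   list(od_600 = tibble::tibble(time_h = tg,
#'                                value = sigmoid_value(sigmoid_params(1.5, 0.5, 7.2), tg))),
#'   tsample_h = 0.5)
#' @export
ncis_experiment <- function(curves, channel_info = NULL, tsample_h = 0.5,
                            reference = "od_600", metadata = list()) {
  if (is.data.frame(curves)) {
    if (!all(c("channel", "time_h", "value") %in% names(curves))) {
      ncis_abort("Long-format `curves` need columns `channel`, `time_h`, `value`.",
                 "ncis_invalid_input")
    }
    curves <- split(as_tibble(curves)[c("time_h", "value")], curves$channel)
  }
  if (!is.list(curves) || length(curves) == 0 || is.null(names(curves)) ||
      any(names(curves) == "")) {
    ncis_abort("`curves` must be a non-empty named list of channel tibbles.",
               "ncis_invalid_input")
  }
  if (anyDuplicated(names(curves)) > 0) {
    ncis_abort("Channel labels must be unique.", "ncis_invalid_input")
  }
  curves <- purrr::map(curves, function(x) {
    x <- as_tibble(x)[c("time_h", "value")]
    x[order(x$time_h), ]
  })
  stopifnot_positive(tsample_h, "tsample_h")

  if (is.null(channel_info)) {
    channel_info <- tibble(
      channel = names(curves),
      units = NA_character_,
      invert = FALSE,
      role = ifelse(names(curves) == reference, "od", "impedance")
    )
  } else {
    channel_info <- as_tibble(channel_info)
    needed <- c("channel", "invert", "role")
    if (!all(needed %in% names(channel_info))) {
      ncis_abort("`channel_info` needs columns `channel`, `invert`, `role`.",
                 "ncis_invalid_input")
    }
    if (!"units" %in% names(channel_info)) channel_info$units <- NA_character_
    missing_info <- setdiff(names(curves), channel_info$channel)
    if (length(missing_info) > 0) {
      ncis_abort(sprintf("`channel_info` is missing channel(s): %s.",
                         paste(missing_info, collapse = ", ")),
                 "ncis_invalid_input")
    }
  }

  structure(
    list(curves = curves, channel_info = channel_info,
         tsample_h = tsample_h, reference = reference, metadata = metadata),
    class = "ncis_experiment"
  )
}

#' @export
print.ncis_experiment <- function(x, ...) {
  cat(sprintf("NCIS growth experiment: %d channel(s), tsample = %g h, reference = %s\n",
              length(x$curves), x$tsample_h, x$reference))
  for (ch in names(x$curves)) {
    info <- x$channel_info[x$channel_info$channel == ch, ]
    cat(sprintf("  %-14s %4d points on [%.2g, %.2g] h  role=%s%s\n",
                ch, nrow(x$curves[[ch]]),
                min(x$curves[[ch]]$time_h), max(x$curves[[ch]]$time_h),
                info$role[1], if (isTRUE(info$invert[1])) " (inverted)" else ""))
  }
  invisible(x)
}

#' Long-format view of an experiment's channels
#'
#' @param exp An [ncis_experiment()].
#' @return A tibble with columns `channel`, `time_h`, `value`.
#' @export
experiment_curves <- function(exp) {
  if (!inherits(exp, "ncis_experiment")) {
    ncis_abort("`exp` must be an ncis_experiment.", "ncis_invalid_input")
  }
  imap(exp$curves, ~ mutate(.x, channel = .y)) |>
    bind_rows() |>
    select("channel", "time_h", "value")
}

#' Compare impedance channels against the optical benchmark
#'
#' Runs the full comparison workflow on a growth experiment: fits the sigmoid
#' growth law to every channel (raw values; falling channels keep their
#' negative amplitude), computes each channel's delay relative to the reference
#' channel from the fitted lags, then — for every non-reference channel —
#' slot-averages the channel around the (delay-aligned) OD sampling times and
#' regresses the slot means against OD inside the valid OD window.
#'
#' @param exp An [ncis_experiment()].
#' @param reference Reference channel label; defaults to the experiment's.
#' @param od_range Closed OD window for the regression (default
#'   `c(0.16, 1.3)`).
#' @param align_delay If `TRUE` (default), the slot windows for a channel are
#'   centred at `od_time + tdelay` so channels leading the reference are paired
#'   with the growth stage the reference sees later, mirroring the delay-shifted
#'   presentation of impedance-versus-OD data.
#' @return An object of class `ncis_comparison`; its `channels` element is a
#'   tibble with per-channel sigmoid parameters, `tdelay`, regression `slope`,
#'   `intercept`, `r_squared`, `n_points` and `n_excluded`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' exp <- ncis_scenario("s_epidermidis_bottle")
#' compare_experiment(exp)
#' @export
compare_experiment <- function(exp, reference = NULL,
                               od_range = c(0.16, 1.3), align_delay = TRUE) {
  if (!inherits(exp, "ncis_experiment")) {
    ncis_abort("`exp` must be an ncis_experiment.", "ncis_invalid_input")
  }
  reference <- reference %||% exp$reference
  if (!reference %in% names(exp$curves)) {
    ncis_abort(sprintf("Reference channel `%s` is not present.", reference),
               "ncis_invalid_input")
  }

  fits <- lapply(names(exp$curves), function(ch) {
    tryCatch(fit_sigmoid(exp$curves[[ch]]), error = function(e) {
      ncis_abort(sprintf("Channel `%s`: %s", ch, conditionMessage(e)),
                 class(e)[1])
    })
  })
  names(fits) <- names(exp$curves)
  t0_ref <- fits[[reference]]$params$t0
  od_curve <- exp$curves[[reference]]

  rows <- imap(exp$curves, function(curve, ch) {
    info <- exp$channel_info[exp$channel_info$channel == ch, ]
    p <- fits[[ch]]$params
    tdelay <- delay_vs_reference(p$t0, t0_ref)
    row <- tibble(
      channel = ch,
      role = info$role[1],
      invert = isTRUE(info$invert[1]),
      ua = p$ua, tau = p$tau, t0 = p$t0,
      tdelay = tdelay,
      slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
      n_points = NA_integer_, n_excluded = NA_integer_
    )
    if (ch == reference) return(row)
    centres <- od_curve$time_h + if (align_delay) tdelay else 0
    slots <- slot_average(curve, centres, exp$tsample_h)
    paired <- tibble(od = od_curve$value, ncis_mean = slots$mean)
    reg <- tryCatch(regress_vs_od(paired, od_range), error = function(e) NULL)
    if (!is.null(reg)) {
      row$slope <- reg$slope
      row$intercept <- reg$intercept
      row$r_squared <- reg$r_squared
      row$n_points <- as.integer(reg$n_points)
      row$n_excluded <- as.integer(reg$n_excluded)
    }
    row
  })

  structure(
    list(
      channels = bind_rows(rows),
      reference = reference,
      od_range = od_range,
      tsample_h = exp$tsample_h,
      align_delay = align_delay,
      fits = fits,
      experiment = exp
    ),
    class = "ncis_comparison"
  )
}

#' @export
print.ncis_comparison <- function(x, ...) {
  cat(sprintf("NCIS vs %s comparison (OD range [%g, %g])\n",
              x$reference, x$od_range[1], x$od_range[2]))
  df <- x$channels
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s tau = %5.3g h  t0 = %6.4g h  tdelay = %+.3g h",
                df$channel[i], df$tau[i], df$t0[i], df$tdelay[i]))
    if (!is.na(df$r_squared[i])) {
      cat(sprintf("  R^2 = %.4f (n = %d)", df$r_squared[i], df$n_points[i]))
    }
    cat("\n")
  }
  invisible(x)
}
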