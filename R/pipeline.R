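#' Subtract a baseline record from a curve or spectrum series
#'
#' Shifts a time series so the record at `baseline_time` becomes exactly zero.
#' For tables carrying a `freq_hz` column (spectrum series), the subtraction is
#' done per frequency with that frequency's own baseline value. The record used
#' as baseline is the one whose time is closest to `baseline_time`; applying
#' the operation twice with the same `baseline_time` is idempotent.
#'
#' @param x A tibble with columns `time_h` and `value`, optionally `freq_hz`.
#' @param baseline_time Time in hours; must lie within the recorded window.
#' @return `x` with `value` shifted per group.
#' @examples
#' curve <- tibble::tibble(time_h = 0:5, value = c(3, 3, 4, 6, 9, 13))
#' subtract_baseline(curve, baseline_time = 0)
#' @export
subtract_baseline <- function(x, baseline_time) {
  if (!is.data.frame(x) || !all(c("time_h", "value") %in% names(x))) {
    ncis_abort("`x` needs columns `time_h` and `value`.", "ncis_invalid_input")
  }
  stopifnot_finite(baseline_time, "baseline_time")
  if (baseline_time < min(x$time_h) || baseline_time > max(x$time_h)) {
    ncis_abort(sprintf(
      "`baseline_time` = %g h is outside the recorded window [%g, %g] h.",
      baseline_time, min(x$time_h), max(x$time_h)),
      "ncis_invalid_input")
  }
  shift_group <- function(df) {
    base <- df$value[which.min(abs(df$time_h - baseline_time))]
    mutate(df, value = .data$value - base)
  }
  if ("freq_hz" %in% names(x)) {
    x |> group_by(.data$freq_hz) |> dplyr::group_modify(~ shift_group(.x)) |>
      ungroup()
  } else {
    shift_group(as_tibble(x))
  }
}

normalize_values <- function(value, invert = FALSE) {
  rng <- range(value)
  if (diff(rng) == 0) {
    ncis_abort("Curve is constant; min-max normalisation is undefined.",
               "ncis_degenerate_data")
  }
  out <- (value - rng[1]) / diff(rng)
  if (invert) 1 - out else out
}

#' Min-max normalise a growth curve
#'
#' Maps a curve's values to `[0, 1]` via `(u - umin) / (umax - umin)`. With
#' `invert = TRUE` the complement `1 - uN` is returned, used for optical
#' reflection channels whose raw response falls during growth so that all
#' normalised channels rise together.
#'
#' @param curve A tibble with columns `time_h` and `value`.
#' @param invert Reverse the normalised direction (for falling channels).
#' @return The curve with `value` replaced by its normalised version.
#' @examples
#' normalize_curve(tibble::tibble(time_h = 1:3, value = c(2, 4, 6)))
#' @export
normalize_curve <- function(curve, invert = FALSE) {
  if (!is.data.frame(curve) || !all(c("time_h", "value") %in% names(curve))) {
    ncis_abort("`curve` needs columns `time_h` and `value`.",
               "ncis_invalid_input")
  }
  mutate(as_tibble(curve), value = normalize_values(.data$value, invert))
}

#' Delay of a channel relative to a reference channel
#'
#' Difference of fitted time lags, `t0_channel - t0_reference`, in hours.
#' Negative values mean the channel responds before the reference; impedance
#' channels sensitive to wall growth typically lead optical density by one to
#' three hours.
#'
#' @param t0_channel,t0_reference Fitted time lags in hours.
#' @return Delay in hours.
#' @examples
#' delay_vs_reference(5.6, 7.2)   # -1.6 h
#' @export
delay_vs_reference <- function(t0_channel, t0_reference) {
  stopifnot_finite(t0_channel, "t0_channel")
  stopifnot_finite(t0_reference, "t0_reference")
  t0_channel - t0_reference
}

#' Average an impedance series in time slots around optical-density samples
#'
#' For each OD sampling time `t_i`, computes mean, standard deviation and count
#' of the impedance points falling in the closed window
#' `[t_i - tsample/2, t_i + tsample/2]`. A point lying on a boundary shared by
#' two windows is assigned to the earlier slot. Empty slots are reported with
#' `n = 0` and `NA` statistics, not dropped.
#'
#' @param ncis A tibble with columns `time_h` and `value` (the continuously
#'   recorded impedance channel).
#' @param od_times Numeric vector of OD sampling times in hours.
#' @param tsample OD sampling period in hours (> 0).
#' @return A tibble with columns `od_time_h`, `mean`, `sd`, `n`.
#' @examples
#' x <- tibble::tibble(time_h = seq(0, 2, 0.1), value = seq(0, 2, 0.1)^2)
#' slot_average(x, od_times = c(0.5, 1.5), tsample = 0.5)
#' @export
slot_average <- function(ncis, od_times, tsample) {
  if (!is.data.frame(ncis) || !all(c("time_h", "value") %in% names(ncis))) {
    ncis_abort("`ncis` needs columns `time_h` and `value`.",
               "ncis_invalid_input")
  }
  stopifnot_positive(tsample, "tsample")
  stopifnot_finite(od_times, "od_times")
  ord <- order(od_times)
  centres <- od_times[ord]
  half <- tsample / 2
  # earliest qualifying slot per point (deterministic boundary tie-break)
  slot <- rep(NA_integer_, nrow(ncis))
  for (i in seq_along(centres)) {
    in_window <- is.na(slot) &
      ncis$time_h >= centres[i] - half & ncis$time_h <= centres[i] + half
    slot[in_window] <- i
  }
  stats <- purrr::map(seq_along(centres), function(i) {
    v <- ncis$value[which(slot == i)]
    if (length(v) == 0) {
      tibble(od_time_h = centres[i], mean = NA_real_, sd = NA_real_, n = 0L)
    } else {
      tibble(od_time_h = centres[i], mean = mean(v),
             sd = if (length(v) > 1) sd(v) else 0, n = length(v))
    }
  }) |> bind_rows()
  # restore the caller's ordering of od_times
  stats[match(seq_along(od_times), ord), ]
}

#' Linear regression of an impedance channel against optical density
#'
#' Ordinary least squares of slot-averaged impedance values against OD,
#' restricted to the OD window where the optical benchmark is linear in cell
#' concentration (default `[0.16, 1.3]`, closed on both ends). Pairs outside
#' the window are excluded and counted.
#'
#' @param paired A tibble with columns `od` and `ncis_mean`.
#' @param od_range Length-2 numeric OD window (closed interval).
#' @return A tibble with `slope`, `intercept`, `r_squared`, `n_points` (pairs
#'   used) and `n_excluded`.
#' @examples
#' d <- tibble::tibble(od = seq(0.2, 1.2, 0.1), ncis_mean = 2 + 3 * seq(0.2, 1.2, 0.1))
#' regress_vs_od(d)
#' @export
regress_vs_od <- function(paired, od_range = c(0.16, 1.3)) {
  if (!is.data.frame(paired) || !all(c("od", "ncis_mean") %in% names(paired))) {
    ncis_abort("`paired` needs columns `od` and `ncis_mean`.",
               "ncis_invalid_input")
  }
  keep <- stats::complete.cases(paired[c("od", "ncis_mean")]) &
    paired$od >= od_range[1] & paired$od <= od_range[2]
  used <- paired[keep, ]
  if (nrow(used) < 3) {
    ncis_abort(sprintf(
      "Only %d pairs fall in the OD range [%g, %g]; at least 3 are required.",
      nrow(used), od_range[1], od_range[2]),
      "ncis_insufficient_data")
  }
  fit <- lm(ncis_mean ~ od, data = used)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((used$ncis_mean - mean(used$ncis_mean))^2)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n_points = nrow(used),
    n_excluded = sum(!keep)
  )
}
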