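test_that("sigmoid law has the right midpoint, limits and monotonicity", {
  p <- sigmoid_params(ua = 4550, tau = 0.25, t0 = 6.0)
  expect_equal(sigmoid_value(p, 6.0), 2275)
  expect_equal(sigmoid_value(p, -1e3), 0, tolerance = 1e-12)
  expect_equal(sigmoid_value(p, 1e3), 4550)
  tg <- seq(0, 12, 0.1)
  expect_true(all(diff(sigmoid_value(p, tg)) > 0))
  # negative amplitude flips direction
  pn <- sigmoid_params(ua = -10, tau = 1, t0 = 17.2)
  expect_true(all(diff(sigmoid_value(pn, tg)) < 0))
  expect_error(sigmoid_params(0, 1, 1), class = "ncis_invalid_input")
  expect_error(sigmoid_params(1, 0, 1), class = "ncis_invalid_input")
})

test_that("sigmoid fitting recovers parameters and rejects degenerate curves", {
  truth <- sigmoid_params(ua = -10.0, tau = 1.0, t0 = 17.2)
  curve <- sigmoid_curve(truth, seq(12, 22, length.out = 80))
  fit <- fit_sigmoid(curve)
  expect_equal(fit$params$ua, truth$ua, tolerance = 1e-6)
  expect_equal(fit$params$tau, truth$tau, tolerance = 1e-6)
  expect_equal(fit$params$t0, truth$t0, tolerance = 1e-6)
  expect_lt(fit$resid_rms, 1e-8)

  # 1% multiplicative noise: median tau over replicates within 10% of truth
  taus <- vapply(1:25, function(s) {
    fit_sigmoid(sigmoid_curve(truth, seq(12, 22, length.out = 100),
                              rel_noise = 0.01, seed = s))$params$tau
  }, numeric(1))
  expect_lt(abs(median(taus) / truth$tau - 1), 0.10)

  flat <- tibble::tibble(time_h = 1:10, value = rep(2, 10))
  expect_error(fit_sigmoid(flat), class = "ncis_degenerate_data")
  expect_error(fit_sigmoid(tibble::tibble(time_h = 1:3, value = 1:3)),
               class = "ncis_insufficient_data")
  expect_error(fit_sigmoid(tibble::tibble(time_h = c(1, 1, 2, 3), value = 1:4)),
               class = "ncis_invalid_input")
})

test_that("wall radius shrinks with the cube root of volume growth", {
  expect_equal(wall_radius(5.0, t0w = 5.6, tau_u = 1, r2 = 0.04), 0.04)
  expect_equal(wall_radius(5.6 + 3, t0w = 5.6, tau_u = 1, r2 = 0.04),
               0.04 / exp(1))
  tg <- seq(0, 20, 0.05)
  r <- wall_radius(tg, 5.6, 1, 0.04)
  expect_true(all(diff(r) <= 0))
  # continuity at the lag
  expect_equal(wall_radius(5.6 - 1e-9, 5.6, 1, 0.04),
               wall_radius(5.6 + 1e-9, 5.6, 1, 0.04), tolerance = 1e-6)
})

test_that("two-region response matches the parallel-conductance oracle", {
  geom <- two_region_geometry(r2 = 0.04, h = 0.0823, rho_a1 = 3.5, rho_a2 = 1)
  # homogeneous medium: independent of r1
  expect_equal(two_region_re_dz(geom, 2, 2, 0.01),
               0.0823 * 2 / (pi * 0.04^2))
  expect_equal(two_region_re_dz(geom, 2, 2, 0.03),
               two_region_re_dz(geom, 2, 2, 0.01))
  # no wall region
  expect_equal(two_region_re_dz(geom, 3, 7, 0.04), 0.0823 * 3 / (pi * 0.04^2))
  # randomized geometries against conductances of the two cylinders
  draws <- withr::with_seed(42, tibble::tibble(
    rho1 = runif(50, 0.1, 5), rho2 = runif(50, 0.1, 5),
    r1 = runif(50, 1e-4, 0.04)))
  direct <- two_region_re_dz(geom, draws$rho1, draws$rho2, draws$r1)
  g1 <- pi * draws$r1^2 / (0.0823 * draws$rho1)
  g2 <- pi * (0.04^2 - draws$r1^2) / (0.0823 * draws$rho2)
  expect_equal(direct, 1 / (g1 + g2), tolerance = 1e-12)
  expect_error(two_region_re_dz(geom, 1, 1, 0.05),
               class = "ncis_invalid_geometry")
})

test_that("unified growth law is continuous, reduces to the sigmoid, and saturates at Un * rho_ratio", {
  draws <- withr::with_seed(99, tibble::tibble(
    un = runif(20, 0.5, 2), tau_u = runif(20, 0.2, 2),
    t0w = runif(20, 2, 8), dt = runif(20, 0, 3),
    rho = 10^runif(20, -1, 1)))
  for (i in seq_len(nrow(draws))) {
    p <- unified_params(draws$un[i], draws$tau_u[i], draws$t0w[i],
                        draws$t0w[i] + draws$dt[i], draws$rho[i])
    # branch agreement at t0w (the mixing weight is exactly 1 there) and
    # continuity across the switch
    sig <- p$un / (1 + exp(-(p$t0w - p$t0b) / p$tau_u))
    expect_equal(unified_growth(p, p$t0w), sig, tolerance = 1e-12)
    expect_lt(abs(unified_growth(p, p$t0w - 1e-9) - unified_growth(p, p$t0w + 1e-9)),
              1e-6 * p$un * max(1, p$rho))
    # sigmoid reduction before the wall lag
    t_pre <- p$t0w - c(0.1, 1, 3)
    expect_equal(unified_growth(p, t_pre),
                 p$un / (1 + exp(-(t_pre - p$t0b) / p$tau_u)))
    # saturation at Un * rho_ratio, exact in the long-time limit
    expect_equal(unified_growth(p, p$t0w + 50 * p$tau_u), p$un * p$rho,
                 tolerance = 1e-9)
  }
})

test_that("the resistivity ratio shifts the normalized half-rise with the same lags", {
  tg <- seq(0, 14, 0.01)
  hi <- unified_growth(unified_params(1, 1.0, 5.6, 7.2, 3.5), tg)
  lo <- unified_growth(unified_params(1, 1.0, 5.6, 7.2, 0.7), tg)
  # both curves grow monotonically to Un * rho_ratio
  expect_true(all(diff(hi) >= -1e-12))
  # late-time levels stand in the ratio of the resistivity ratios
  p_hi <- unified_params(1, 1.0, 5.6, 7.2, 3.5)
  p_lo <- unified_params(1, 1.0, 5.6, 7.2, 0.7)
  expect_equal(unified_growth(p_hi, 60) / unified_growth(p_lo, 60), 3.5 / 0.7,
               tolerance = 1e-9)
  # with shared lags, the high-ratio curve's rise is dominated by the slower
  # wall-mixing weight (time scale 3 tau_u / 2), so its normalized half-rise
  # trails the low-ratio curve's by a fraction of an hour
  half_rise <- function(v) tg[which(v >= min(v) + 0.5 * diff(range(v)))[1]]
  expect_gt(half_rise(hi), half_rise(lo))
  expect_lt(half_rise(hi) - half_rise(lo), 1)
})

test_that("two-stage unified fit fixes lags from the stage-1 sigmoid fits", {
  tg <- seq(0, 14, length.out = 200)
  lo <- unified_curve(unified_params(1, 1.0, 5.6, 7.2, 3.5), tg)
  hi <- sigmoid_curve(sigmoid_params(1, 1.0, 7.2), tg)
  fit <- fit_unified(lo, hi)
  expect_equal(fit$t0w, fit$stage1$low$params$t0)
  expect_equal(fit$t0b, fit$stage1$high$params$t0)
  expect_equal(fit$tau_u, fit$stage1$high$params$tau)
  expect_false(fit$diagnostics$lag_order_warning)
  # swapped curves trip the lag-order diagnostic without silent reordering
  expect_warning(swapped <- fit_unified(hi, lo), "swapped")
  expect_true(swapped$diagnostics$lag_order_warning)
})

test_that("joint refinement recovers unified-law parameters from generated pairs", {
  tg <- seq(0, 14, length.out = 200)
  lo <- unified_curve(unified_params(1, 1.0, 3.7, 5.4, 3.5), tg)
  hi <- unified_curve(unified_params(1, 1.0, 3.7, 5.4, 0.5), tg)
  fit <- suppressWarnings(fit_unified(lo, hi, joint_refit = TRUE))
  expect_equal(fit$tau_u, 1.0, tolerance = 1e-3)
  expect_equal(fit$t0w, 3.7, tolerance = 1e-3)
  expect_equal(fit$t0b, 5.4, tolerance = 1e-3)
  expect_equal(fit$curves$rho_ratio[fit$curves$curve == "low"], 3.5,
               tolerance = 1e-3)
  expect_equal(fit$curves$rho_ratio[fit$curves$curve == "high"], 0.5,
               tolerance = 1e-3)

  # with 1% noise the lags stay within 0.2 h and the ratio within 15%
  stats <- vapply(1:20, function(s) {
    lon <- unified_curve(unified_params(1, 1.0, 3.7, 5.4, 3.5), tg,
                         rel_noise = 0.01, seed = s)
    hin <- unified_curve(unified_params(1, 1.0, 3.7, 5.4, 0.5), tg,
                         rel_noise = 0.01, seed = s + 500)
    f <- suppressWarnings(fit_unified(lon, hin, joint_refit = TRUE))
    c(f$t0w, f$t0b, f$curves$rho_ratio[f$curves$curve == "low"])
  }, numeric(3))
  expect_lt(abs(median(stats[1, ]) - 3.7), 0.2)
  expect_lt(abs(median(stats[2, ]) - 5.4), 0.2)
  expect_lt(abs(median(stats[3, ]) / 3.5 - 1), 0.15)
})
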