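test_that("complex RC impedance has the right DC limit and resistances", {
  geom <- cell_geometry(10.6)
  # omega -> 0: Z -> Kcell / kappa, imaginary part vanishes
  z <- impedance_rc(geom, kappa = 1.49, freq = 1e-6)
  expect_equal(Re(z), 10.6 / 1.49, tolerance = 1e-9)
  expect_equal(Re(z), 7.11, tolerance = 1e-3)
  expect_lt(abs(Im(z)), 1e-6)

  expect_equal(solution_resistance(geom, 1.75), 10.6 / 1.75)
  expect_equal(solution_resistance(geom, 1.75), 6.06, tolerance = 1e-3)

  # general shape: positive real part, non-positive imaginary part
  pts <- in_band_points(50, seed = 7)
  z <- impedance_rc(bottle_params(), pts$kappa, pts$freq)
  expect_true(all(Re(z) > 0))
  expect_true(all(Im(z) <= 0))

  expect_error(impedance_rc(geom, -1, 1e4), class = "ncis_invalid_input")
  expect_error(impedance_rc(geom, 1, 0), class = "ncis_invalid_input")
  expect_error(solution_resistance(geom, 0), class = "ncis_invalid_input")
})

test_that("closed-form impedance changes equal the complex-difference oracle", {
  p <- bottle_params()
  pts <- in_band_points(100, seed = 11)
  z0 <- impedance_rc(p, pts$kappa, pts$freq)
  zb <- impedance_rc(p, rep(p$kappa_b, 100), pts$freq)
  dz <- z0 - zb
  expect_lt(max(abs(Re(dz) - delta_z_real(p, pts$kappa, pts$freq)) / abs(Re(dz))),
            1e-10)
  expect_lt(max(abs(-Im(dz) - delta_z_neg_imag(p, pts$kappa, pts$freq)) / abs(Im(dz))),
            1e-10)
})

test_that("real impedance change peaks at the peak conductivity with height 1/(2 omega C1)", {
  # single-solution term: baseline conductivity sent to (numerically) zero
  p <- circuit_params(c1 = 2.0e-12, eps_r = 78, kappa_b = 0)
  for (f in c(1e4, 3e5, 3e8)) {
    kd <- peak_conductivity(f)
    expect_equal(delta_z_real(p, kd, f), 1 / (2 * 2 * pi * f * p$c1),
                 tolerance = 1e-9)
    # argmax on a fine log grid sits at kd within grid resolution
    grid <- kd * 10^seq(-2, 2, length.out = 2001)
    vals <- delta_z_real(p, grid, f)
    expect_equal(grid[which.max(vals)], kd, tolerance = 1e-2)
    # log-symmetry: kappa and (omega eps_r eps0)^2 / kappa give equal values
    k <- kd * 10^seq(-1.5, 1.5, length.out = 21)
    expect_equal(delta_z_real(p, k, f), delta_z_real(p, kd^2 / k, f),
                 tolerance = 1e-12)
  }
  # 300 MHz, C1 = 2 pF: peak height about 132.6 ohm
  expect_equal(delta_z_real(p, peak_conductivity(3e8), 3e8), 132.6,
               tolerance = 1e-3)
  # identical solution and baseline gives exactly zero
  pb <- circuit_params(c1 = 2e-12, kappa_b = 1e-3)
  expect_identical(delta_z_real(pb, 1e-3, 1e5), 0)
})

test_that("negative imaginary change is monotone with the capacitive saturation limit", {
  p <- circuit_params(c1 = 6.0e-12, kappa_b = 1e-9)
  f <- 1e5
  # kappa0 -> Inf with kappa_b -> 0: value -> -1/(omega C1)
  expect_equal(delta_z_neg_imag(p, 1e9, f), -1 / (2 * pi * f * p$c1),
               tolerance = 1e-6)
  grid <- 10^seq(-8, 2, length.out = 200)
  vals <- delta_z_neg_imag(p, grid, f)
  expect_true(all(diff(vals) < 0))
  pb <- circuit_params(c1 = 6e-12, kappa_b = 1e-3)
  expect_identical(delta_z_neg_imag(pb, 1e-3, f), 0)
})

test_that("peak conductivity matches the reference checkpoints and scales linearly", {
  expect_equal(signif(peak_conductivity(1e4), 2), 4.3e-5)
  expect_equal(signif(peak_conductivity(3e8), 2), 1.3)
  expect_equal(peak_conductivity(2e5), 2 * peak_conductivity(1e5))
  expect_error(peak_conductivity(0), class = "ncis_invalid_input")
})

test_that("sensitivity band spans two decades centred on the peak conductivity", {
  band <- sensitivity_band(c(1e4, 1e6))
  kd <- peak_conductivity(c(1e4, 1e6))
  expect_equal(band$kappa_low, kd / 10)
  expect_equal(band$kappa_high, kd * 10)
  expect_equal(band$kappa_high / band$kappa_low, rep(100, 2))
  expect_equal(sqrt(band$kappa_low * band$kappa_high), kd)
  expect_equal(signif(sensitivity_band(1e4)$kappa_low, 2), 4.3e-6)
})

test_that("capacitance and cell constant convert consistently", {
  expect_equal(cell_constant_from_c1(2.0e-12), 345, tolerance = 1e-2)
  kc <- 10.6
  expect_equal(cell_constant_from_c1(c1_from_cell_constant(kc)), kc,
               tolerance = 1e-12)
  expect_error(cell_constant_from_c1(0), class = "ncis_invalid_input")
})

test_that("C1 calibration recovers the generating capacitance", {
  p <- bottle_params()
  # noise-free: exact recovery
  sw <- gen_sweep(p, bottle_freqs, bottle_kappas)
  fit <- fit_circuit(sw)
  expect_equal(fit$params$c1, 6.0e-12, tolerance = 1e-6)
  expect_lt(fit$diagnostics$residual_norm, 1e-9)

  # at the reported noise levels, bias < 1% and RMSE < 2% over 50 replicates
  rel_err <- vapply(1:50, function(s) {
    swn <- gen_sweep(p, bottle_freqs, bottle_kappas,
                     noise = noise_spec(0.007, 0.0004, seed = s))
    fit_circuit(swn)$params$c1 / 6.0e-12 - 1
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.01)
  expect_lt(sqrt(mean(rel_err^2)), 0.02)

  # tidy/glance surface
  td <- generics::tidy(fit)
  expect_equal(td$term, "c1")
  expect_equal(generics::glance(fit)$kcell, cell_constant_from_c1(fit$params$c1))
})

test_that("degenerate sweeps are rejected with informative classes", {
  p <- bottle_params()
  one_kappa <- gen_sweep(p, bottle_freqs, 1e-3)
  expect_error(fit_circuit(one_kappa), class = "ncis_insufficient_data")
  # a single solution equal to the baseline: all-zero impedance changes
  zero_sweep <- tibble::tibble(
    freq_hz = bottle_freqs, kappa_s_per_m = p$kappa_b * (1 + 1e-15),
    re_dz_ohm = 0, neg_im_dz_ohm = 0)
  expect_error(fit_circuit(zero_sweep, kappa_b = p$kappa_b),
               class = "ncis_insufficient_data")
  dup <- dplyr::bind_rows(one_kappa, one_kappa)
  expect_error(fit_circuit(dup), class = "ncis_invalid_input")
})
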