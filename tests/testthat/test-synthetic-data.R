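test_that("sweep generator is exact at zero noise and seed-deterministic", {
  p <- bottle_params()
  sw <- gen_sweep(p, bottle_freqs, bottle_kappas)
  expect_equal(sw$re_dz_ohm, delta_z_real(p, sw$kappa_s_per_m, sw$freq_hz))
  expect_equal(sw$neg_im_dz_ohm,
               delta_z_neg_imag(p, sw$kappa_s_per_m, sw$freq_hz))

  n1 <- gen_sweep(p, bottle_freqs, bottle_kappas, noise_spec(0.007, 4e-4, seed = 3))
  n2 <- gen_sweep(p, bottle_freqs, bottle_kappas, noise_spec(0.007, 4e-4, seed = 3))
  n3 <- gen_sweep(p, bottle_freqs, bottle_kappas, noise_spec(0.007, 4e-4, seed = 4))
  expect_identical(n1$re_dz_ohm, n2$re_dz_ohm)
  expect_false(identical(n1$re_dz_ohm, n3$re_dz_ohm))

  expect_error(gen_sweep(p, bottle_freqs, bottle_kappas, noise_spec(0.01, 0.01)),
               class = "ncis_invalid_input")
  expect_error(gen_sweep(p, numeric(0), bottle_kappas),
               class = "ncis_invalid_input")
})

test_that("generated noise is multiplicative with the requested relative spread", {
  p <- bottle_params()
  kappas <- 10^seq(-5, 0, length.out = 250)
  exact <- gen_sweep(p, bottle_freqs, kappas)
  noisy <- gen_sweep(p, bottle_freqs, kappas, noise_spec(0.007, 0.0004, seed = 12))
  rel_re <- noisy$re_dz_ohm / exact$re_dz_ohm - 1
  rel_im <- noisy$neg_im_dz_ohm / exact$neg_im_dz_ohm - 1
  expect_lt(abs(sd(rel_re) / 0.007 - 1), 0.10)
  expect_lt(abs(sd(rel_im) / 0.0004 - 1), 0.10)
  expect_lt(abs(mean(rel_re)), 0.002)  # mean-one multiplicative noise
})

test_that("growth-experiment generator reproduces its models and sampling design", {
  models <- list(
    od_600 = sigmoid_params(1.5, 0.5, 7.2),
    re_dz_15khz = sigmoid_params(5000, 0.5, 5.6),
    or_800 = sigmoid_params(-0.2, 0.5, 5.1))
  tg <- seq(0, 14, 0.05)
  exp <- gen_growth_experiment(models, tg, od_interval = 0.5,
                               or_channels = "or_800", od_jitter = 0)
  # noise-free channels equal the forward models bit-for-bit
  expect_identical(exp$curves$re_dz_15khz$value,
                   sigmoid_value(models$re_dz_15khz, tg))
  # OD point count ~ span / interval + 1
  expect_equal(nrow(exp$curves$od_600), 14 / 0.5 + 1)
  # metadata flags: OR inverted, roles assigned
  info <- exp$channel_info
  expect_true(info$invert[info$channel == "or_800"])
  expect_equal(info$role[info$channel == "od_600"], "od")
  # noise-free sigmoid recovery from each channel
  for (ch in names(models)) {
    f <- fit_sigmoid(exp$curves[[ch]])
    expect_equal(f$params$tau, models[[ch]]$tau, tolerance = 1e-6)
    expect_equal(f$params$t0, models[[ch]]$t0, tolerance = 1e-6)
  }

  # 1% noise over replicate experiments: t0 estimates are tight (sd < 0.1 h)
  t0s <- vapply(1:25, function(s) {
    e <- gen_growth_experiment(models, tg, od_interval = 0.5,
                               noise = noise_spec(0.01, seed = s),
                               or_channels = "or_800")
    fit_sigmoid(e$curves$re_dz_15khz)$params$t0
  }, numeric(1))
  expect_lt(sd(t0s), 0.1)

  expect_error(gen_growth_experiment(list(), tg), class = "ncis_invalid_input")
  expect_error(gen_growth_experiment(models, tg, noise = noise_spec(0.01, seed = NULL)),
               class = "ncis_invalid_input")
})

test_that("temperature traces propagate to negligible conductivity factors", {
  tg <- seq(0, 10, 0.01)
  still <- gen_temperature_trace(temperature_spec(37, 0), tg)
  expect_true(all(still$kappa_factor == 1))

  tr <- gen_temperature_trace(temperature_spec(37, 0.011, seed = 2),
                              seq_len(1e4) / 100)
  # at the recorded stability, 3 sigma stays near the 0.1% level
  expect_lt(max(abs(tr$kappa_factor - 1)), 0.02 * 0.011 * 5)
  expect_lt(abs(sd(tr$temp_c) / 0.011 - 1), 0.05)
  expect_error(gen_temperature_trace(temperature_spec(37, 0.1), tg),
               class = "ncis_invalid_input")
})

test_that("scenario presets produce analysable objects", {
  sw <- ncis_scenario("kcl_sweep_bottle")
  expect_equal(fit_circuit(sw)$params$c1, 6.0e-12, tolerance = 1e-9)
  sw2 <- ncis_scenario("kcl_sweep_wellplate", seed = 1)
  expect_equal(fit_circuit(sw2)$params$c1, 2.0e-12, tolerance = 0.05)

  exp <- ncis_scenario("s_epidermidis_wellplate")
  f <- fit_sigmoid(exp$curves$re_dz_160mhz)
  expect_equal(f$params$ua, -10.0, tolerance = 1e-4)
  expect_equal(f$params$t0, 17.2, tolerance = 1e-6)
})
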