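# shared builders for synthetic fixtures; everything is generated in code

bottle_params <- function() circuit_params(c1 = 6.0e-12, kappa_b = 5.5e-6)
wellplate_params <- function() circuit_params(c1 = 2.0e-12, kappa_b = 1e-4)

bottle_freqs <- c(1e4, 5e4, 3e5, 1e6)
bottle_kappas <- 10^seq(log10(5.5e-6), log10(1.7), length.out = 7)

sigmoid_curve <- function(params, times, rel_noise = 0, seed = NULL) {
  v <- sigmoid_value(params, times)
  if (rel_noise > 0) {
    stopifnot(!is.null(seed))
    v <- withr::with_seed(seed, v * (1 + rel_noise * rnorm(length(v))))
  }
  tibble::tibble(time_h = times, value = v)
}

unified_curve <- function(params, times, rel_noise = 0, seed = NULL) {
  v <- unified_growth(params, times)
  if (rel_noise > 0) {
    stopifnot(!is.null(seed))
    v <- withr::with_seed(seed, v * (1 + rel_noise * rnorm(length(v))))
  }
  tibble::tibble(time_h = times, value = v)
}

# random conductivities inside the decade sensitivity band of each frequency,
# where sweep measurements are actually taken
in_band_points <- function(n, seed, f_range = c(4, 8.5)) {
  withr::with_seed(seed, {
    f <- 10^runif(n, f_range[1], f_range[2])
    k <- peak_conductivity(f) * 10^runif(n, -1, 1)
    list(freq = f, kappa = k)
  })
}
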