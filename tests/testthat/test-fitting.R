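test_that("noise estimation is unbiased and baseline-insensitive", {
  acq <- acq_full(n_averages = 8)
  set.seed(11)
  flat <- gaussian_spectrum(acq, 0, 3, 0.03, noise_sd = 2)
  est <- estimate_noise_sd(flat)
  expect_equal(est, 2, tolerance = 0.15)

  sloped <- mrs_spectrum(flat$values + complex(real = 5 * flat$ppm + 40),
                         flat$ppm, flat$larmor_per_ppm)
  expect_equal(estimate_noise_sd(sloped), est, tolerance = 0.01)

  zero <- mrs_spectrum(complex(real = numeric(2048)), ppm_axis(acq),
                       acq$larmor_per_ppm)
  expect_lt(estimate_noise_sd(zero), 1e-12)
  expect_error(estimate_noise_sd(flat, c(8.50, 8.51)), "20 points")
})

test_that("a clean single Gaussian is recovered exactly", {
  acq <- acq_full(n_averages = 8)
  spec <- gaussian_spectrum(acq, 1, 3.0, 0.02, slope = 0.5, intercept = 2)
  fit <- fit_peak_model(spec, "gaba_sg", noise_sd = 0.25)
  expect_true(fit$converged)
  expect_equal(fit$amplitudes, 1, tolerance = 1e-6)
  expect_equal(fit$centers, 3.0, tolerance = 1e-6)
  expect_equal(fit$width_sigma, 0.02, tolerance = 1e-5)
  expect_equal(fit$baseline_slope, 0.5, tolerance = 1e-4)
  expect_lt(fit$fit_error_pct, 1e-6)
  expect_equal(fit$integral, 0.02 * sqrt(2 * pi), tolerance = 1e-5)
  # SNR is height / (2 noise_sd) by definition
  expect_equal(fit$snr, 1 / (2 * 0.25), tolerance = 1e-6)
  expect_equal(fit$fwhm_hz, 2 * sqrt(2 * log(2)) * 0.02 * 127.7322,
               tolerance = 1e-5)
})

test_that("the pseudo-doublet prefers the double Gaussian model", {
  acq <- acq_full(n_averages = 8)
  truth_integral <- 2 * 0.8 * 0.022 * sqrt(2 * pi)
  spec <- gaussian_spectrum(acq, c(0.8, 0.8), c(2.94, 3.06), 0.022)
  dg <- fit_peak_model(spec, "gaba_dg")
  sg <- fit_peak_model(spec, "gaba_sg")
  expect_equal(dg$integral, truth_integral, tolerance = 0.005)
  expect_equal(dg$centers, c(2.94, 3.06), tolerance = 1e-4)
  expect_gt(sg$residual_sd, dg$residual_sd)
})

test_that("fits are window-translation equivariant", {
  acq <- acq_full(n_averages = 8)
  shift <- 13 * 2000 / (2048 * 127.7322)  # whole number of bins
  s1 <- gaussian_spectrum(acq, c(0.6, 0.6), c(2.94, 3.06), 0.02)
  s2 <- gaussian_spectrum(acq, c(0.6, 0.6), c(2.94, 3.06) + shift, 0.02)
  m1 <- peak_model_spec("gaba_dg")
  m2 <- m1
  m2$window <- m1$window + shift
  m2$centers <- m1$centers + shift
  f1 <- fit_peak_model(s1, m1)
  f2 <- fit_peak_model(s2, m2)
  expect_equal(f2$centers, f1$centers + shift, tolerance = 1e-8)
  expect_equal(f2$amplitudes, f1$amplitudes, tolerance = 1e-8)
  expect_equal(f2$width_sigma, f1$width_sigma, tolerance = 1e-8)
  expect_equal(f2$integral, f1$integral, tolerance = 1e-8)
})

test_that("doublet integral recovery stays within 10% across the SNR range", {
  acq <- acq_full(n_averages = 8)
  truth_integral <- 2 * 0.8 * 0.022 * sqrt(2 * pi)
  set.seed(31)
  for (snr_target in c(5, 10, 20)) {
    noise_sd <- 0.8 / (2 * snr_target)  # height ~ component amplitude
    errs <- vapply(1:20, function(i) {
      spec <- gaussian_spectrum(acq, c(0.8, 0.8), c(2.94, 3.06), 0.022,
                                noise_sd = noise_sd)
      fit <- fit_peak_model(spec, "gaba_dg", noise_sd)
      abs(fit$integral - truth_integral) / truth_integral
    }, numeric(1))
    expect_lt(median(errs), 0.10)
  }
})

test_that("reference Lorentzians report linewidth and scale correctly", {
  acq <- acq_full(n_averages = 8)
  spec <- lorentzian_spectrum(acq, 100, 2.01, fwhm_hz = 9.0)
  fit <- fit_reference(spec, "naa")
  expect_equal(fit$fwhm_hz, 9.0, tolerance = 0.05 / 9)
  expect_equal(fit$centers, 2.01, tolerance = 1e-5)

  spec2 <- mrs_spectrum(2 * spec$values, spec$ppm, spec$larmor_per_ppm)
  fit2 <- fit_reference(spec2, "naa")
  expect_equal(fit2$integral, 2 * fit$integral, tolerance = 1e-6)
  expect_equal(fit2$fwhm_hz, fit$fwhm_hz, tolerance = 1e-6)
})

test_that("the water reference amplitude is recovered within 1%", {
  acq <- acq_params(n_averages = 8)
  ds <- simulate_dataset(acq, ndm = quiet_ndm(), seed = 1,
                         water_amplitude = 1000, water_lw_hz = 8)
  wspec <- fid_to_spectrum(ds$water[1, ], acq)
  fit <- fit_reference(wspec, "water")
  # analytic height of a sampled Lorentzian decay
  height <- 1000 / (1 - exp(-pi * 8 / 2000))
  expect_equal(fit$amplitudes, height, tolerance = 0.01)
  expect_equal(fit$centers, 4.68, tolerance = 1e-3)
})

test_that("creatine and choline are separated by the joint fit", {
  acq <- acq_params(n_averages = 8)
  ds <- simulate_dataset(acq, singlet_table(), quiet_ndm(), seed = 1)
  cs <- hadamard_combine(ds)
  cr <- fit_reference(cs$sum, "cr")
  cho <- fit_reference(cs$sum, "cho")
  expect_equal(cr$centers, 3.03, tolerance = 1e-3)
  expect_equal(cho$centers, 3.20, tolerance = 1e-3)
  # amplitudes in the simulator's 10:8 proportion
  expect_equal(cr$amplitudes / cho$amplitudes, 10 / 8, tolerance = 0.02)
  expect_lt(cr$fit_error_pct, 1)
})
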