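test_that("line broadening composes exponentially and sets the linewidth", {
  acq <- acq_full()
  t <- time_axis(acq)
  fid <- exp(complex(imaginary = 2 * pi * 100 * t))
  expect_identical(line_broaden(fid, 0, acq), fid)
  expect_equal(line_broaden(line_broaden(fid, 3, acq), 3, acq),
               line_broaden(fid, 6, acq), tolerance = 1e-12)
  expect_error(line_broaden(fid, -1, acq), ">= 0")

  # measure FWHM on an 8x zero-padded transform (independent of
  # fid_to_spectrum): an undamped line broadened by 3 Hz reads 3 Hz
  lb <- line_broaden(fid, 3, acq)
  padded <- c(lb, complex(real = numeric(7 * length(lb))))
  spec <- Re(fft(padded))  # absorptive part carries the 3 Hz FWHM
  df <- acq$sampling_rate / length(padded)
  half <- max(spec) / 2
  above <- which(spec >= half)
  fwhm_hz <- (max(above) - min(above)) * df
  expect_equal(fwhm_hz, 3, tolerance = 2 * df / 3 + 0.05)
})

test_that("eddy-current correction removes exactly the water phase", {
  acq <- acq_small(n_points = 256)
  t <- time_axis(acq)
  fid <- exp(complex(real = -5 * t, imaginary = 2 * pi * 40 * t))
  water_pos <- complex(real = exp(-3 * t))
  expect_equal(eddy_current_correct(fid, water_pos), fid, tolerance = 1e-14)

  out <- eddy_current_correct(fid, fid)
  expect_lt(max(abs(Arg(out))), 1e-12)

  # shared time-varying phase corruption vanishes
  corruption <- exp(complex(imaginary = 0.8 * sin(2 * pi * 3 * t)))
  got <- eddy_current_correct(fid * corruption, water_pos * corruption)
  expect_lt(max(Mod(got - fid)), 1e-10)

  w0 <- water_pos
  w0[5] <- 0
  expect_warning(eddy_current_correct(fid, w0), "zero-magnitude")
  expect_error(eddy_current_correct(fid, water_pos[-1]), "equal length")
})

test_that("registration recovers injected offsets and is null-safe", {
  acq <- acq_params(n_averages = 32)
  ds0 <- simulate_dataset(acq, ndm = quiet_ndm(), seed = 1)
  reg0 <- register_averages(ds0)
  expect_lt(reg0$report$delta_delta0, 1e-4)

  t <- time_axis(acq)
  ds5 <- ds0
  ds5$fids[3, ] <- ds5$fids[3, ] * exp(complex(imaginary = 2 * pi * 5 * t))
  reg5 <- register_averages(ds5)
  expect_equal(reg5$report$per_average_freq[3], 5, tolerance = 0.01 / 5)
  expect_lt(max(abs(reg5$report$per_average_freq[-3])), 0.01)

  dsp <- ds0
  dsp$fids[6, ] <- dsp$fids[6, ] * exp(complex(imaginary = pi / 2))
  regp <- register_averages(dsp)
  expect_equal(regp$report$per_average_phase[6], pi / 2,
               tolerance = 0.01 / (pi / 2))
  expect_error(register_averages(head_averages(ds0, 4)), ">= 2")
})

test_that("registration reduces across-average variance on drifted data", {
  acq <- acq_params(n_averages = 64)
  ds <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 21)
  reg <- register_averages(ds)
  row_var <- function(m) {
    mu <- colMeans(m)
    mean(Mod(sweep(m, 2, mu))^2)
  }
  expect_lt(row_var(reg$dataset$fids), row_var(ds$fids) * 1.01)
})

test_that("estimated drift metric tracks the injected offsets", {
  acq <- acq_params(n_averages = 32)
  rel_err <- vapply(1:20, function(seed) {
    ds <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 100 + seed)
    reg <- register_averages(ds)
    injected <- mean(abs(attr(ds, "true_freq_ppm")))
    abs(reg$report$delta_delta0 - injected) / injected
  }, numeric(1))
  expect_lt(mean(rel_err), 0.30)
  expect_lt(max(rel_err), 0.50)
})

test_that("line broadening commutes with the registration correction", {
  acq <- acq_params(n_averages = 16)
  ds <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 4)
  reg <- register_averages(ds)
  t <- time_axis(acq)
  corr <- exp(complex(imaginary =
    -2 * pi * reg$report$per_average_freq[2] * t -
      reg$report$per_average_phase[2]))
  a <- line_broaden(ds$fids[2, ] * corr, 3, acq)
  b <- line_broaden(ds$fids[2, ], 3, acq) * corr
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("preprocessing emits an aligned dataset and an offset report", {
  acq <- acq_params(n_averages = 16)
  ds <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 9)
  pp <- preprocess_dataset(ds)
  expect_s3_class(pp$dataset, "hermes_dataset")
  expect_length(pp$report$per_average_freq, 16)
  expect_gte(pp$report$delta_delta0, 0)
})
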