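test_that("ppm axis has the documented spacing, span and centre", {
  acq <- acq_full()
  ax <- ppm_axis(acq)
  expect_length(ax, 2048)
  # spacing = sampling_rate / (n_points * larmor_per_ppm)
  expect_equal(unique(round(diff(ax), 12)),
               2000 / (2048 * 127.7322), tolerance = 1e-6)
  expect_equal(ax[2048 / 2 + 1], 3.0)
  # half-span = (sampling_rate/2) / larmor_per_ppm ~ 7.828 ppm
  half_bw <- (2000 / 2) / 127.7322
  expect_equal(3.0 - min(ax), half_bw, tolerance = 1e-12)
  expect_equal(max(ax) - 3.0, half_bw - diff(ax)[1], tolerance = 1e-12)
  expect_equal(half_bw, 7.828, tolerance = 1e-3)

  wide <- acq_params(larmor_per_ppm = 2 * 127.7322)
  expect_equal(diff(range(ppm_axis(wide))), diff(range(ax)) / 2,
               tolerance = 1e-12)
})

test_that("Hz/ppm conversion round-trips exactly", {
  acq <- acq_full()
  for (hz in c(-731.2, 0, 1.5, 127.7322, 640)) {
    expect_equal(ppm_to_hz(hz_to_ppm(hz, acq), acq), hz, tolerance = 1e-12)
  }
})

test_that("acquisition parameter invariants are enforced", {
  expect_error(acq_params(n_points = 2000), "power of two")
  expect_error(acq_params(n_averages = 318), "divisible by 4")
  expect_error(acq_params(te = 3, tr = 2), "smaller")
  expect_error(acq_params(subexperiment_cycle = c("A", "B", "C", "E")),
               "labels")
})

test_that("spectrum transform places a known sinusoid at the right shift", {
  acq <- acq_full()
  fid <- exp(complex(imaginary = 2 * pi * 127.7322 * time_axis(acq)))
  s <- fid_to_spectrum(fid, acq)
  peak_ppm <- s$ppm[which.max(Mod(s$values))]
  expect_lt(abs(peak_ppm - 4.0), diff(s$ppm)[1])
})

test_that("spectrum transform is linear and power-conserving", {
  acq <- acq_small()
  set.seed(1)
  for (rep in 1:5) {
    x <- complex(real = rnorm(64), imaginary = rnorm(64))
    y <- complex(real = rnorm(64), imaginary = rnorm(64))
    a <- rnorm(1); b <- rnorm(1)
    lhs <- fid_to_spectrum(a * x + b * y, acq)$values
    rhs <- a * fid_to_spectrum(x, acq)$values +
      b * fid_to_spectrum(y, acq)$values
    expect_lt(max(Mod(lhs - rhs)), 1e-10 * max(Mod(rhs)))
    # unnormalized forward DFT: sum |fid|^2 == mean |spectrum|^2
    expect_equal(sum(Mod(x)^2), mean(Mod(fid_to_spectrum(x, acq)$values)^2),
                 tolerance = 1e-10)
  }
  expect_true(all(fid_to_spectrum(complex(real = numeric(64)),
                                  acq)$values == 0))
  expect_error(fid_to_spectrum(complex(real = numeric(32)), acq), "samples")
})

test_that("bundles round-trip bit-exactly and reject malformed input", {
  acq <- acq_small()
  ds <- simulate_dataset(acq, resonances = default_resonance_table(),
                         ndm = noise_drift_model(), seed = 5,
                         subject_id = "s1", region = "ACC",
                         tissue = tissue_fractions(0.4, 0.4, 0.2))
  dir <- withr::local_tempdir()
  save_bundle(ds, dir)
  back <- load_bundle(dir)
  expect_identical(back$fids, ds$fids)
  expect_identical(back$water, ds$water)
  expect_identical(back$subexperiment, ds$subexperiment)
  expect_equal(back$acq, ds$acq)
  expect_equal(back$tissue, ds$tissue)
  # second round trip is a fixed point
  dir2 <- withr::local_tempdir()
  save_bundle(back, dir2)
  expect_identical(load_bundle(dir2)$fids, ds$fids)

  # drop one FID row -> shape diagnostic
  lines <- readLines(file.path(dir, "fids.csv"))
  writeLines(lines[-length(lines)], file.path(dir, "fids.csv"))
  expect_error(load_bundle(dir), "declares")

  # unknown sub-experiment label -> label diagnostic
  hdr <- jsonlite::read_json(file.path(dir2, "header.json"),
                             simplifyVector = TRUE)
  hdr$subexperiment[1] <- "E"
  jsonlite::write_json(hdr, file.path(dir2, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_bundle(dir2), "unknown sub-experiment")

  expect_error(load_bundle(withr::local_tempdir()), "missing header")
})

test_that("dataset constructor enforces balance and tissue sums", {
  acq <- acq_small()
  m <- matrix(complex(real = 0), 8, 64)
  expect_error(hermes_dataset(acq, m, rep(c("A", "B"), 4), m[1, , drop = FALSE]),
               "balanced")
  expect_error(tissue_fractions(0.5, 0.5, 0.5), "sum to 1")
  expect_error(head_averages(
    hermes_dataset(acq, m, rep(c("A", "B", "C", "D"), 2),
                   m[1, , drop = FALSE]), 6), "balance")
})
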