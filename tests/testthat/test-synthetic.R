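test_that("resonance table encodes the editing scheme", {
  neo <- default_resonance_table("neonate")
  adult <- default_resonance_table("adult")
  expect_false("mm" %in% neo$metabolite)
  expect_gt(adult$amplitude[adult$metabolite == "mm"], 0)

  singlets <- neo[neo$metabolite %in% c("naa", "cr", "cho", "water_resid"), ]
  mods <- as.matrix(singlets[, c("mod_a", "mod_b", "mod_c", "mod_d")])
  expect_true(all(mods == 1))

  gaba <- neo[neo$metabolite == "gaba", ]
  expect_true(all(gaba$mod_a == 1 & gaba$mod_b == 1 &
                    gaba$mod_c == -1 & gaba$mod_d == -1))
  gsh <- neo[neo$metabolite == "gsh", ]
  expect_true(all(gsh$mod_a == 1 & gsh$mod_b == -1 &
                    gsh$mod_c == 1 & gsh$mod_d == -1))
  # doublet centred on 3 ppm, split by 15 Hz
  expect_equal(mean(gaba$delta), 3.0)
  expect_equal(diff(gaba$delta) * 127.7322, 15, tolerance = 1e-6)
  expect_error(default_resonance_table("foetal"))
})

test_that("simulator honours degenerate inputs and determinism", {
  acq <- acq_small()
  empty <- default_resonance_table()[0, ]
  ds0 <- simulate_dataset(acq, empty, quiet_ndm(), seed = 1)
  expect_true(all(ds0$fids == 0))
  expect_equal(as.integer(table(ds0$subexperiment)), rep(2L, 4))

  a <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 7)
  b <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 7)
  c <- simulate_dataset(acq, ndm = noise_drift_model(), seed = 8)
  expect_identical(a$fids, b$fids)
  expect_false(identical(a$fids, c$fids))
  expect_gte(nrow(a$water), 1)
})

test_that("a lone resonance lands within one bin of its chemical shift", {
  acq <- acq_params(n_averages = 8)
  tab <- resonance("x", "x", 3.57, 1, 8)
  ds <- simulate_dataset(acq, tab, quiet_ndm(), seed = 1)
  s <- fid_to_spectrum(ds$fids[1, ], acq)
  expect_lt(abs(s$ppm[which.max(Mod(s$values))] - 3.57), diff(s$ppm)[1])
})

test_that("non-edited content is identical across sub-experiments", {
  acq <- acq_small(n_points = 512)
  ds <- simulate_dataset(acq, singlet_table(), quiet_ndm(), seed = 1)
  specs <- lapply(c("A", "B", "C", "D"), function(e)
    fid_to_spectrum(ds$fids[which(ds$subexperiment == e)[1], ], acq)$values)
  top <- max(Mod(specs[[1]]))
  for (i in 2:4) expect_lt(max(Mod(specs[[i]] - specs[[1]])), 1e-10 * top)

  # an edited resonance does modulate
  dsg <- simulate_dataset(acq, unit_gaba_resonance(), quiet_ndm(), seed = 1)
  sa <- fid_to_spectrum(dsg$fids[which(dsg$subexperiment == "A")[1], ], acq)
  sc <- fid_to_spectrum(dsg$fids[which(dsg$subexperiment == "C")[1], ], acq)
  expect_equal(max(Re(sa$values)), max(-Re(sc$values)), tolerance = 1e-10)
})

test_that("averaging N acquisitions shrinks spectral noise as 1/sqrt(N)", {
  acq <- acq_params(n_averages = 64, n_points = 256)
  empty <- default_resonance_table()[0, ]
  ratio <- vapply(1:50, function(seed) {
    ds <- simulate_dataset(acq, empty,
                           noise_drift_model(1, 0, 0, 0), seed = seed)
    sd_one <- sd(Re(fid_to_spectrum(ds$fids[1, ], acq)$values))
    sd_mean <- sd(Re(fid_to_spectrum(colMeans(ds$fids), acq)$values))
    sd_one / sd_mean
  }, numeric(1))
  expect_equal(mean(ratio), sqrt(64), tolerance = 0.1)
})

test_that("cohort simulation produces truth rows and collapses when quiet", {
  cfg <- cohort_config(n_subjects = 3, between_subject_cv = 0,
                       tissue_sd = c(gm = 0, wm = 0, csf = 0),
                       noise_drift = quiet_ndm())
  coh <- simulate_cohort(cfg, acq_small(), seed = 3)
  expect_equal(nrow(coh$truth), 3 * 3)
  expect_identical(coh$datasets[[1]]$fids, coh$datasets[[2]]$fids)
  expect_identical(coh$datasets[[2]]$fids, coh$datasets[[3]]$fids)
  # neonatal GABA+ scale rides at 0.16 mM by default
  expect_equal(unique(coh$truth$true_conc[coh$truth$metabolite == "gaba"]),
               0.16)
  expect_error(cohort_config(n_subjects = 0))
})
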