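#!/usr/bin/env Rscript
# One simulated subject, end to end: shows the editing scheme at work.
# Simulates a default neonatal HERMES acquisition (320 averages, 2 kHz /
# 2048 points, TE/TR 80/2000 ms), preprocesses it (eddy-current correction,
# spectral registration, 3 Hz line broadening), Hadamard-combines the four
# sub-experiments and writes the reconstructed spectra plus the per-average
# offset report.
#
# Outputs: results/example/combined_spectra.csv, offsets.csv, fits.csv

library(hermesneo)

out_dir <- "results/example"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

acq <- acq_params()
ds <- simulate_dataset(acq, seed = 101, subject_id = "example",
                       region = "ACC",
                       tissue = tissue_fractions(0.35, 0.45, 0.20))
pp <- preprocess_dataset(ds)
cs <- hadamard_combine(pp$dataset)
write_combined_csv(cs, file.path(out_dir, "combined_spectra.csv"))

offsets <- data.frame(average = seq_along(pp$report$per_average_freq),
                      freq_hz = pp$report$per_average_freq,
                      phase_rad = pp$report$per_average_phase)
write.csv(offsets, file.path(out_dir, "offsets.csv"), row.names = FALSE)

fb <- fit_battery(cs)
rows <- do.call(rbind, lapply(names(fb), function(m) {
  f <- fb[[m]]
  data.frame(model = m, integral = f$integral, snr = f$snr,
             fit_error_pct = f$fit_error_pct, fwhm_hz = f$fwhm_hz)
}))
write.csv(rows, file.path(out_dir, "fits.csv"), row.names = FALSE)

message(sprintf("drift metric delta-delta0: %.4f ppm (injected %.4f)",
                pp$report$delta_delta0,
                mean(abs(attr(ds, "true_freq_ppm")))))
message(sprintf("GABA+ (double Gaussian): SNR %.1f, fit error %.1f%%",
                fb$gaba_dg$snr, fb$gaba_dg$fit_error_pct))
message(sprintf("NAA linewidth: %.1f Hz; wrote tables to %s", fb$naa$fwhm_hz,
                out_dir))
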