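# shared fixtures: small acquisitions keep the suite fast; full-size ones
# are used only where the spectral grid matters

acq_small <- function(n_averages = 8, n_points = 64) {
  acq_params(n_averages = n_averages, n_points = n_points)
}

acq_full <- function(n_averages = 320) acq_params(n_averages = n_averages)

quiet_ndm <- function() noise_drift_model(0, 0, 0, 0)

# single fully GABA-modulated unit resonance
unit_gaba_resonance <- function(delta = 3.0, lw = 10) {
  resonance("g", "gaba", delta, 1, lw, mod_a = 1, mod_b = 1,
            mod_c = -1, mod_d = -1)
}

# non-edited singlets only (drop edited rows and residual water)
singlet_table <- function() {
  tab <- default_resonance_table("neonate")
  tab[tab$metabolite %in% c("naa", "cr", "cho"), ]
}

# direct frequency-domain Gaussian(s) + optional linear baseline on an axis
gaussian_spectrum <- function(acq, amps, centers, sigma, slope = 0,
                              intercept = 0, noise_sd = 0) {
  ppm <- ppm_axis(acq)
  y <- slope * ppm + intercept
  for (i in seq_along(amps)) {
    y <- y + amps[i] * exp(-(ppm - centers[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  mrs_spectrum(complex(real = y), ppm, acq$larmor_per_ppm)
}

lorentzian_spectrum <- function(acq, amp, center, fwhm_hz) {
  ppm <- ppm_axis(acq)
  g <- (fwhm_hz / acq$larmor_per_ppm) / 2
  y <- amp * g^2 / ((ppm - center)^2 + g^2)
  mrs_spectrum(complex(real = y), ppm, acq$larmor_per_ppm)
}
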