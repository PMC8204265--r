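#' Resonance tables for the HERMES signal model
#'
#' Each row describes one Lorentzian line: chemical shift, amplitude
#' (signal units, proportional to concentration times effective proton
#' visibility), time-domain decay expressed as a Lorentzian FWHM in Hz,
#' phase, and a per-sub-experiment editing modulation factor in \[-1, 1\].
#' Non-edited singlets carry +1 in all four sub-experiments and therefore
#' cancel in both difference combinations; resonances coupled to the 1.9 ppm
#' editing target (GABA+, Glx) flip sign between \{A,B\} and \{C,D\}, and the
#' 4.56 ppm target (GSH) flips between \{A,C\} and \{B,D\}.
#'
#' @param name Row label.
#' @param metabolite Grouping label used by cohort scaling (e.g. both GABA+
#'   doublet components map to \code{"gaba"}).
#' @param delta Centre chemical shift in ppm.
#' @param amplitude Signal amplitude (arbitrary units).
#' @param lw_hz Lorentzian FWHM in Hz; the time-domain decay constant is
#'   \code{1 / (pi * lw_hz)} seconds.
#' @param phase Phase in radians.
#' @param mod_a,mod_b,mod_c,mod_d Editing modulation per sub-experiment.
#' @return A tibble with one row per line.
#' @export
resonance <- function(name, metabolite, delta, amplitude, lw_hz, phase = 0,
                      mod_a = 1, mod_b = 1, mod_c = 1, mod_d = 1) {
  stopifnot(lw_hz > 0, all(abs(c(mod_a, mod_b, mod_c, mod_d)) <= 1))
  tibble::tibble(name = name, metabolite = metabolite, delta = delta,
                 amplitude = amplitude, lw_hz = lw_hz, phase = phase,
                 mod_a = mod_a, mod_b = mod_b, mod_c = mod_c, mod_d = mod_d)
}

#' Default neonatal / adult resonance table
#'
#' The neonatal mode models the key observation that the edited 3 ppm GABA+
#' signal is a resolved pseudo-doublet: two equal components split by
#' \code{doublet_sep_hz} with no co-edited macromolecule (MM) background. In
#' adult mode a broad co-edited MM component centred at 3 ppm fills the
#' doublet notch, so the summed GABA+ region approximates a single hump.
#'
#' Relative amplitudes are chosen so that, at the default noise level of
#' [noise_drift_model()], full-length acquisitions land in the quality regime
#' typical of in vivo neonatal HERMES (edited GABA+ SNR well below 10, Glx
#' roughly twice GABA+, GSH in between). The GABA+ amplitude corresponds to
#' the default true concentration of 0.16 mM via [cohort_config()].
#'
#' @param mode \code{"neonate"} or \code{"adult"}.
#' @param doublet_sep_hz Splitting of the GABA+ pseudo-doublet in Hz.
#' @param larmor_per_ppm Hz per ppm used to express the splitting in ppm.
#' @return A tibble of resonances (see [resonance()]).
#' @export
default_resonance_table <- function(mode = c("neonate", "adult"),
                                    doublet_sep_hz = 15,
                                    larmor_per_ppm = 42.5774 * 3) {
  mode <- match.arg(mode)
  half_sep <- (doublet_sep_hz / larmor_per_ppm) / 2
  gaba_mod <- c(1, 1, -1, -1)   # edited by the 1.9 ppm pulse
  gsh_mod <- c(1, -1, 1, -1)    # edited by the 4.56 ppm pulse
  tab <- rbind(
    resonance("naa", "naa", 2.01, 12.0, 6.0),
    resonance("cr3", "cr", 3.03, 10.0, 6.0),
    resonance("cr39", "cr", 3.91, 6.7, 6.0),
    resonance("cho", "cho", 3.20, 8.0, 6.0),
    resonance("gaba_lo", "gaba", 3.00 - half_sep, 0.8, 10,
              mod_a = gaba_mod[1], mod_b = gaba_mod[2],
              mod_c = gaba_mod[3], mod_d = gaba_mod[4]),
    resonance("gaba_hi", "gaba", 3.00 + half_sep, 0.8, 10,
              mod_a = gaba_mod[1], mod_b = gaba_mod[2],
              mod_c = gaba_mod[3], mod_d = gaba_mod[4]),
    resonance("glx_lo", "glx", 3.71, 1.3, 9,
              mod_a = gaba_mod[1], mod_b = gaba_mod[2],
              mod_c = gaba_mod[3], mod_d = gaba_mod[4]),
    resonance("glx_hi", "glx", 3.79, 1.3, 9,
              mod_a = gaba_mod[1], mod_b = gaba_mod[2],
              mod_c = gaba_mod[3], mod_d = gaba_mod[4]),
    resonance("gsh", "gsh", 2.95, 1.1, 11,
              mod_a = gsh_mod[1], mod_b = gsh_mod[2],
              mod_c = gsh_mod[3], mod_d = gsh_mod[4]),
    resonance("water_resid", "water_resid", 4.68, 3.0, 12)
  )
  if (mode == "adult") {
    # broad co-edited MM background under the 3 ppm GABA+ signal
    tab <- rbind(tab, resonance("mm3", "mm", 3.00, 1.6, 30,
                                mod_a = 1, mod_b = 1, mod_c = -1, mod_d = -1))
  }
  tab
}
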