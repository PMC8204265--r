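#' Noise and frequency/phase instability model
#'
#' Describes the stochastic imperfections applied per transient: additive
#' complex white noise, a slow linear frequency drift, and random
#' per-average frequency/phase jitter emulating residual subject motion
#' after prospective (scanner-side) frequency correction.
#'
#' The default jitter standard deviation is set so the mean absolute
#' per-average frequency offset is close to 0.03 ppm, the scale reported for
#' unsedated neonates: with offsets ~ N(drift(t), s), E|offset| is
#' approximately s * sqrt(2/pi) = 0.030 ppm for s = 0.0375 ppm plus a small
#' drift contribution.
#'
#' @param noise_sd SD of the additive white noise, per complex component per
#'   time-domain point (signal units).
#' @param drift_ppm_per_min Linear frequency drift in ppm per minute.
#' @param jitter_sd_ppm SD of the random per-average frequency offset (ppm).
#' @param phase_jitter_sd SD of the random per-average phase offset (rad).
#' @return An object of class \code{noise_drift_model}.
#' @export
noise_drift_model <- function(noise_sd = 4.0,
                              drift_ppm_per_min = 0.001,
                              jitter_sd_ppm = 0.0375,
                              phase_jitter_sd = 0.2) {
  stopifnot(noise_sd >= 0, jitter_sd_ppm >= 0, phase_jitter_sd >= 0)
  structure(list(noise_sd = noise_sd, drift_ppm_per_min = drift_ppm_per_min,
                 jitter_sd_ppm = jitter_sd_ppm,
                 phase_jitter_sd = phase_jitter_sd),
            class = "noise_drift_model")
}

# Noiseless, offset-free FID of one sub-experiment:
# x(t) = sum_k a_k * mod_k(e) * exp(2i*pi*nu_k*t - t/tau_k + i*phi_k),
# nu_k = (delta_k - tx_ppm) * larmor_per_ppm, tau_k = 1/(pi*lw_k).
ideal_fid <- function(resonances, acq, subexperiment) {
  t <- time_axis(acq)
  x <- complex(real = numeric(acq$n_points))
  if (nrow(resonances) == 0L) return(x)
  modcol <- paste0("mod_", tolower(subexperiment))
  for (k in seq_len(nrow(resonances))) {
    r <- resonances[k, ]
    nu <- (r$delta - acq$tx_ppm) * acq$larmor_per_ppm
    x <- x + r$amplitude * r[[modcol]] *
      exp(complex(real = -pi * r$lw_hz * t,
                  imaginary = 2 * pi * nu * t + r$phase))
  }
  x
}

#' Simulate one HERMES dataset
#'
#' Generates \code{acq$n_averages} transients cycling the four editing
#' sub-experiments in \code{acq$subexperiment_cycle} order. Each transient is
#' the sum of Lorentzian lines (see [default_resonance_table()]) multiplied
#' by its editing modulation, then shifted by that average's frequency/phase
#' offset (linear drift plus jitter drawn from \code{ndm}) and degraded with
#' complex white noise. One clean (offset- and noise-free) unsuppressed-water
#' reference FID is attached.
#'
#' @param acq An [acq_params()].
#' @param resonances Resonance tibble; see [resonance()].
#' @param ndm A [noise_drift_model()].
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param subject_id,region,tissue Metadata stored on the dataset.
#' @param water_amplitude Amplitude of the unsuppressed water reference line
#'   at 4.68 ppm.
#' @param water_lw_hz Lorentzian FWHM of the water reference in Hz.
#' @return A [hermes_dataset()] with attributes \code{true_freq_ppm} and
#'   \code{true_phase_rad} holding the injected per-average offsets.
#' @export
simulate_dataset <- function(acq, resonances = default_resonance_table(),
                             ndm = noise_drift_model(), seed = 1,
                             subject_id = "sim", region = "other",
                             tissue = NULL,
                             water_amplitude = 1000, water_lw_hz = 8) {
  set.seed(seed)
  na <- acq$n_averages
  t <- time_axis(acq)
  labels <- rep(acq$subexperiment_cycle, length.out = na)
  base <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(e)
    ideal_fid(resonances, acq, e))

  scan_time_min <- (seq_len(na) - 1) * acq$tr / 60
  freq_ppm <- ndm$drift_ppm_per_min * scan_time_min +
    stats::rnorm(na, 0, ndm$jitter_sd_ppm)
  phase_rad <- stats::rnorm(na, 0, ndm$phase_jitter_sd)

  fids <- matrix(complex(real = 0), na, acq$n_points)
  for (m in seq_len(na)) {
    f_hz <- freq_ppm[m] * acq$larmor_per_ppm
    x <- base[[labels[m]]] *
      exp(complex(imaginary = 2 * pi * f_hz * t + phase_rad[m]))
    if (ndm$noise_sd > 0) {
      x <- x + complex(real = stats::rnorm(acq$n_points, 0, ndm$noise_sd),
                       imaginary = stats::rnorm(acq$n_points, 0, ndm$noise_sd))
    }
    fids[m, ] <- x
  }

  nu_w <- (4.68 - acq$tx_ppm) * acq$larmor_per_ppm
  water <- matrix(water_amplitude *
                    exp(complex(real = -pi * water_lw_hz * t,
                                imaginary = 2 * pi * nu_w * t)),
                  1, acq$n_points)

  ds <- hermes_dataset(acq, fids, labels, water, subject_id = subject_id,
                       region = region, tissue = tissue)
  attr(ds, "true_freq_ppm") <- freq_ppm
  attr(ds, "true_phase_rad") <- phase_rad
  ds
}

#' Cohort configuration for the simulator
#'
#' Defines a group of subjects scanned in one region: true metabolite
#' concentrations, between-subject amplitude scatter, the tissue-fraction
#' distribution of the voxel, and the noise/instability model. Tissue
#' defaults qualitatively reflect the two voxels studied in neonates: an
#' anterior-cingulate voxel with moderate GM and appreciable CSF, and a
#' GM-rich thalamic voxel with near-zero CSF.
#'
#' @param n_subjects Number of subjects.
#' @param region \code{"ACC"}, \code{"thalamus"} or \code{"other"}.
#' @param resonance_mode Passed to [default_resonance_table()].
#' @param true_concentrations Named list, mM, for \code{gaba}, \code{glx},
#'   \code{gsh}. The defaults carry the neonatal GABA+ scale of 0.16 mM.
#' @param tissue_mean,tissue_sd Named numeric (gm, wm, csf): mean and SD of
#'   the per-subject tissue fractions; draws are clipped at 0 and
#'   renormalized to sum to 1. \code{NULL} means use the region default.
#' @param between_subject_cv Log-normal coefficient of variation of the
#'   per-subject, per-metabolite amplitude scale.
#' @param noise_drift A [noise_drift_model()].
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 16,
                          region = "ACC",
                          resonance_mode = "neonate",
                          true_concentrations = list(gaba = 0.16, glx = 4.0,
                                                     gsh = 1.2),
                          tissue_mean = NULL, tissue_sd = NULL,
                          between_subject_cv = 0.10,
                          noise_drift = noise_drift_model()) {
  stopifnot(n_subjects >= 1)
  if (is.null(tissue_mean)) {
    tissue_mean <- switch(region,
      ACC = c(gm = 0.35, wm = 0.45, csf = 0.20),
      thalamus = c(gm = 0.75, wm = 0.23, csf = 0.02),
      c(gm = 0.5, wm = 0.4, csf = 0.1))
  }
  if (is.null(tissue_sd)) tissue_sd <- c(gm = 0.03, wm = 0.03, csf = 0.03)
  structure(list(n_subjects = as.integer(n_subjects), region = region,
                 resonance_mode = resonance_mode,
                 true_concentrations = true_concentrations,
                 tissue_mean = tissue_mean, tissue_sd = tissue_sd,
                 between_subject_cv = between_subject_cv,
                 noise_drift = noise_drift),
            class = "cohort_config")
}

# reference concentrations behind the default amplitude table (mM)
.default_conc <- c(gaba = 0.16, glx = 4.0, gsh = 1.2)

#' Simulate a cohort of HERMES datasets
#'
#' Draws, per subject, a tissue composition and log-normal amplitude scatter
#' around the configured true concentrations, then simulates one dataset per
#' subject. Edited-metabolite amplitudes scale linearly with concentration
#' relative to the defaults of [default_resonance_table()].
#'
#' Signal amplitudes are coupled to the sampled tissue composition the way
#' the voxel physics dictates: metabolite lines scale with the
#' water-density-weighted brain-tissue volume
#' \code{f_gm w_gm + f_wm w_wm} (metabolites are absent from CSF, with no
#' GM/WM concentration ratio assumed), and the unsuppressed-water reference
#' scales with \code{sum_x f_x w_x R(T1w_x, T2w_x)} over all three
#' compartments. Both are normalized to one fixed reference composition
#' (GM/WM/CSF = 0.5/0.4/0.1, independent of region), so regions with
#' different tissue make-up genuinely differ in raw signal. Tissue
#' correction in the quantification stage therefore removes exactly the
#' between-subject variance this coupling injects.
#'
#' @param cfg A [cohort_config()].
#' @param acq An [acq_params()].
#' @param seed Integer seed for the whole cohort.
#' @param cp A [correction_params()] supplying water content and relaxation
#'   for the tissue coupling.
#' @return List with \code{datasets} (list of [hermes_dataset()]) and
#'   \code{truth} (tibble: subject, region, metabolite, true concentration,
#'   realized subject amplitude scale, tissue fractions).
#' @export
simulate_cohort <- function(cfg, acq = acq_params(), seed = 1,
                            cp = correction_params()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max, cfg$n_subjects)
  mets <- names(cfg$true_concentrations)
  sdlog <- sqrt(log(1 + cfg$between_subject_cv^2))

  wc <- cp$water_content
  r_w <- (1 - exp(-cp$tr / cp$water_t1)) * exp(-cp$te / cp$water_t2)
  tissue_sig <- function(f) f[1] * wc[["gm"]] + f[2] * wc[["wm"]]
  water_sig <- function(f) sum(f * wc[c("gm", "wm", "csf")] *
                                 r_w[c("gm", "wm", "csf")])
  f_ref <- c(0.5, 0.4, 0.1)  # fixed across regions so contrasts survive

  datasets <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    f <- pmax(stats::rnorm(3, cfg$tissue_mean, cfg$tissue_sd), 0)
    f <- f / sum(f)
    tissue <- tissue_fractions(f[1], f[2], f[3])
    scale <- stats::rlnorm(length(mets), -sdlog^2 / 2, sdlog)
    names(scale) <- mets
    met_factor <- tissue_sig(f) / tissue_sig(f_ref)
    wat_factor <- water_sig(f) / water_sig(f_ref)

    tab <- default_resonance_table(cfg$resonance_mode,
                                   larmor_per_ppm = acq$larmor_per_ppm)
    is_water <- tab$metabolite == "water_resid"
    tab$amplitude[!is_water] <- tab$amplitude[!is_water] * met_factor
    tab$amplitude[is_water] <- tab$amplitude[is_water] * wat_factor
    for (m in mets) {
      rows <- tab$metabolite == m
      tab$amplitude[rows] <- tab$amplitude[rows] *
        (cfg$true_concentrations[[m]] / .default_conc[[m]]) * scale[[m]]
    }
    sid <- sprintf("%s_%02d", cfg$region, s)
    datasets[[s]] <- simulate_dataset(acq, tab, cfg$noise_drift,
                                      seed = subject_seeds[s],
                                      subject_id = sid, region = cfg$region,
                                      tissue = tissue,
                                      water_amplitude = 1000 * wat_factor)
    truth[[s]] <- tibble::tibble(
      subject = sid, region = cfg$region, metabolite = mets,
      true_conc = unlist(cfg$true_concentrations[mets]),
      amp_scale = scale[mets],
      f_gm = f[1], f_wm = f[2], f_csf = f[3])
  }
  list(datasets = datasets, truth = do.call(rbind, truth))
}
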