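#' Exponential line broadening
#'
#' Multiplies a FID by \code{exp(-pi * lb_hz * t)}, which convolves the
#' spectrum with a Lorentzian of FWHM \code{lb_hz}: a zero-width line
#' acquires exactly that linewidth, and broadening by a then b equals
#' broadening by a + b.
#'
#' @param fid Complex vector (one FID) or complex matrix (one FID per row).
#' @param lb_hz Line broadening in Hz, >= 0.
#' @param acq An [acq_params()] supplying the time axis.
#' @return Same shape as \code{fid}.
#' @export
line_broaden <- function(fid, lb_hz, acq) {
  if (lb_hz < 0) stop("lb_hz must be >= 0")
  w <- exp(-pi * lb_hz * time_axis(acq))
  if (is.matrix(fid)) {
    fid * matrix(w, nrow(fid), ncol(fid), byrow = TRUE)
  } else {
    fid * w
  }
}

#' Klose-style eddy-current correction
#'
#' Subtracts the instantaneous phase of a water-reference FID from the
#' metabolite FID point by point: \code{out[n] = fid[n] *
#' exp(-1i * Arg(water[n]))}. Magnitudes are unchanged. Where the water
#' magnitude is zero its phase is undefined; those points are left untouched
#' with a warning.
#'
#' @param fid Complex vector.
#' @param water_fid Complex vector, same length.
#' @return Complex vector with the water phase removed.
#' @export
eddy_current_correct <- function(fid, water_fid) {
  if (length(fid) != length(water_fid)) {
    stop("fid and water_fid must have equal length")
  }
  zero <- Mod(water_fid) == 0
  ph <- Arg(water_fid)
  if (any(zero)) {
    warning("zero-magnitude water samples: phase left untouched there")
    ph[zero] <- 0
  }
  fid * exp(complex(imaginary = -ph))
}

# Frequency/phase alignment of one FID segment to a reference segment.
# For fixed f the optimal phase is analytic:
#   phi* = -Arg(sum x exp(2i pi f t) Conj(ref)),
# so the least-squares problem reduces to maximizing
# |sum x exp(2i pi f t) Conj(ref)| over f alone: coarse grid, then local
# refinement.
align_one <- function(x, ref, t, f_grid) {
  corr <- function(f) {
    Mod(sum(x * exp(complex(imaginary = 2 * pi * f * t)) * Conj(ref)))
  }
  vals <- vapply(f_grid, corr, numeric(1))
  f0 <- f_grid[which.max(vals)]
  step <- f_grid[2] - f_grid[1]
  opt <- try(stats::optimize(corr, c(f0 - step, f0 + step), maximum = TRUE,
                             tol = 1e-7), silent = TRUE)
  if (inherits(opt, "try-error")) {
    return(list(f = 0, phi = 0, failed = TRUE))
  }
  f <- opt$maximum
  z <- sum(x * exp(complex(imaginary = 2 * pi * f * t)) * Conj(ref))
  list(f = f, phi = -Arg(z), failed = FALSE)
}

# Residual frequency/phase of a sub-experiment mean FID relative to a
# reference, measured on the non-edited NAA singlet: centre from a
# Lorentzian + linear-baseline fit (matched-filter precision, and the
# baseline absorbs tails of edited resonances so they cannot pull the
# estimate), phase from the complex correlation over the NAA window after
# the frequency correction.
naa_frame_offset <- function(fid, ref_win, ref_center, acq, window) {
  fitn <- try(fit_reference(fid_to_spectrum(fid, acq), "naa",
                            window = window), silent = TRUE)
  if (inherits(fitn, "try-error") || !fitn$converged) {
    return(list(f = 0, dphi = 0, failed = TRUE))
  }
  f <- (ref_center - fitn$centers) * acq$larmor_per_ppm
  shifted <- fid * exp(complex(imaginary = 2 * pi * f * time_axis(acq)))
  sw <- crop_spectrum(fid_to_spectrum(shifted, acq), window)
  list(f = f, dphi = -Arg(sum(sw$values * Conj(ref_win$values))),
       failed = FALSE)
}

#' Spectral registration of individual averages
#'
#' Aligns every transient by time-domain least squares: for average m it
#' finds the frequency/phase pair (f, phi) minimizing
#' \code{sum |x_m(t) exp(i(2 pi f t + phi)) - ref(t)|^2} over the first
#' \code{t_fit} seconds of the FID (the tail being noise-dominated).
#'
#' Alignment proceeds in two stages. First, averages are aligned within
#' their own editing sub-experiment: the initial reference is the pointwise
#' median across that sub-experiment's averages (robust to a single badly
#' shifted transient), then the pass is repeated against the mean of the
#' aligned averages. Second, the frames of the four sub-experiments are
#' harmonized: each sub-experiment mean's residual frequency/phase offset is
#' measured on the non-edited NAA singlet (peak position by parabolic
#' interpolation, phase at the peak) relative to the overall mean, so
#' genuine editing differences between sub-experiments cannot masquerade as
#' frequency offsets; this small common-mode correction is applied to every
#' average of the sub-experiment.
#'
#' The report carries, per average, the estimated frequency (Hz) and phase
#' (rad) offsets present in the data (the negatives of the applied
#' corrections), and the summary drift metric \code{delta_delta0}: the mean
#' absolute estimated frequency offset expressed in ppm.
#'
#' @param ds A [hermes_dataset()].
#' @param t_fit Seconds of FID used for alignment.
#' @param f_search Half-width of the frequency search window in Hz.
#' @param n_iter Alignment passes within each sub-experiment (>= 1).
#' @param naa_window ppm window of the NAA singlet used for the
#'   cross-sub-experiment stage.
#' @param summary_fun How to summarize |frequency offsets| into
#'   \code{delta_delta0}: \code{"mean"} (default) or \code{"max"}.
#' @return List with \code{dataset} (aligned copy) and \code{report}, a list
#'   with \code{per_average_freq} (Hz), \code{per_average_phase} (rad),
#'   \code{delta_delta0} (ppm) and \code{failed} (logical per average).
#' @export
register_averages <- function(ds, t_fit = 0.2, f_search = 20, n_iter = 2,
                              naa_window = c(1.85, 2.15),
                              summary_fun = c("mean", "max")) {
  summary_fun <- match.arg(summary_fun)
  counts <- table(ds$subexperiment)
  if (any(counts < 2)) stop("need >= 2 averages per sub-experiment")
  t_full <- time_axis(ds$acq)
  keep <- t_full < t_fit
  t <- t_full[keep]
  f_grid <- seq(-f_search, f_search, by = 0.5)

  fids <- ds$fids
  freq <- numeric(nrow(fids))
  phase <- numeric(nrow(fids))
  failed <- logical(nrow(fids))

  # stage 1: within-sub-experiment alignment
  for (iter in seq_len(n_iter)) {
    for (e in unique(ds$subexperiment)) {
      rows <- which(ds$subexperiment == e)
      seg <- fids[rows, keep, drop = FALSE]
      ref <- if (iter == 1L) {
        complex(real = apply(Re(seg), 2, stats::median),
                imaginary = apply(Im(seg), 2, stats::median))
      } else {
        colMeans(seg)
      }
      for (m in rows) {
        a <- align_one(fids[m, keep], ref, t, f_grid)
        if (a$failed) { failed[m] <- TRUE; next }
        fids[m, ] <- fids[m, ] *
          exp(complex(imaginary = 2 * pi * a$f * t_full + a$phi))
        freq[m] <- freq[m] + a$f
        phase[m] <- phase[m] + a$phi
      }
    }
  }

  # stage 2: harmonize sub-experiment frames on the NAA singlet
  sub_means <- lapply(c("A", "B", "C", "D"), function(e)
    colMeans(fids[ds$subexperiment == e, , drop = FALSE]))
  overall <- Reduce(`+`, sub_means) / 4
  ref_spec <- fid_to_spectrum(overall, ds$acq)
  ref_fit <- fit_reference(ref_spec, "naa", window = naa_window)
  ref_win <- crop_spectrum(ref_spec, naa_window)
  for (i in seq_along(sub_means)) {
    e <- c("A", "B", "C", "D")[i]
    rows <- which(ds$subexperiment == e)
    a <- naa_frame_offset(sub_means[[i]], ref_win, ref_fit$centers, ds$acq,
                          naa_window)
    if (a$failed) { failed[rows] <- TRUE; next }
    corr <- exp(complex(imaginary = 2 * pi * a$f * t_full + a$dphi))
    fids[rows, ] <- fids[rows, , drop = FALSE] *
      matrix(corr, length(rows), length(corr), byrow = TRUE)
    freq[rows] <- freq[rows] + a$f
    phase[rows] <- phase[rows] + a$dphi
  }

  out <- ds
  out$fids <- fids
  # applied correction is +f; the offset present in the data was -f
  est_freq <- -freq
  est_phase <- -phase
  abs_ppm <- abs(est_freq) / ds$acq$larmor_per_ppm
  dd0 <- if (summary_fun == "mean") mean(abs_ppm) else max(abs_ppm)
  list(dataset = out,
       report = list(per_average_freq = est_freq,
                     per_average_phase = est_phase,
                     delta_delta0 = dd0, failed = failed))
}

#' Full per-average preprocessing
#'
#' Applies, in order: eddy-current correction against the water reference
#' (after demodulating the water FID to the carrier so only its instrumental
#' phase is removed), spectral registration, and exponential line
#' broadening. Apodization comes last so it cannot bias the registration.
#'
#' @param ds A [hermes_dataset()].
#' @param lb_hz Line broadening in Hz (default 3).
#' @param ecc Apply eddy-current correction? Default TRUE.
#' @param ... Passed to [register_averages()].
#' @return List with \code{dataset} (preprocessed) and \code{report} (the
#'   registration offset report).
#' @export
preprocess_dataset <- function(ds, lb_hz = 3, ecc = TRUE, ...) {
  if (ecc) {
    w <- ds$water[1, ]
    # remove the water carrier so ECC only subtracts instrumental phase
    spec_w <- fid_to_spectrum(w, ds$acq)
    f_w <- (spec_w$ppm[which.max(Mod(spec_w$values))] - ds$acq$tx_ppm) *
      ds$acq$larmor_per_ppm
    w0 <- w * exp(complex(imaginary = -2 * pi * f_w * time_axis(ds$acq)))
    for (m in seq_len(nrow(ds$fids))) {
      ds$fids[m, ] <- eddy_current_correct(ds$fids[m, ], w0)
    }
  }
  reg <- register_averages(ds, ...)
  out <- reg$dataset
  out$fids <- line_broaden(out$fids, lb_hz, out$acq)
  out$water <- line_broaden(out$water, lb_hz, out$acq)
  list(dataset = out, report = reg$report)
}
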