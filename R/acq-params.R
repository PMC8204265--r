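#' Acquisition parameters for a HERMES single-voxel MRS experiment
#'
#' Bundles the constants that define one edited-MRS acquisition: receiver
#' bandwidth, number of complex points per FID, number of averages, echo and
#' repetition times, field strength and the chemical-shift referencing of the
#' transmitter. Defaults correspond to a 3 T neonatal HERMES protocol: 2 kHz
#' bandwidth, 2048 points, 320 averages, TE/TR = 80/2000 ms, transmitter on
#' the creatine resonance at 3 ppm, and a four-step editing cycle A-B-C-D
#' (A: both editing pulses on, B: 1.9 ppm pulse only, C: 4.56 ppm pulse only,
#' D: both off).
#'
#' @param sampling_rate Receiver bandwidth in Hz.
#' @param n_points Complex points per FID; must be a power of two.
#' @param n_averages Total transients; must be divisible by four so the four
#'   editing sub-experiments are balanced.
#' @param te,tr Echo and repetition time in seconds.
#' @param field_strength Static field in tesla.
#' @param larmor_per_ppm Hz per ppm; defaults to 42.5774 MHz/T times the
#'   field strength.
#' @param tx_ppm Chemical shift of the transmitter (centre of the spectrum).
#' @param subexperiment_cycle Character vector over \code{c("A","B","C","D")}
#'   giving the repeating order of editing sub-experiments.
#'
#' @return An object of class \code{acq_params}.
#' @export
acq_params <- function(sampling_rate = 2000,
                       n_points = 2048,
                       n_averages = 320,
                       te = 0.080,
                       tr = 2.0,
                       field_strength = 3.0,
                       larmor_per_ppm = 42.5774 * field_strength,
                       tx_ppm = 3.0,
                       subexperiment_cycle = c("A", "B", "C", "D")) {
  stopifnot(sampling_rate > 0, larmor_per_ppm > 0, te > 0, tr > 0)
  if (te >= tr) stop("te must be smaller than tr")
  if (n_points < 2 || bitwAnd(n_points, n_points - 1L) != 0L) {
    stop("n_points must be a power of two")
  }
  if (n_averages %% 4L != 0L) stop("n_averages must be divisible by 4")
  if (!all(subexperiment_cycle %in% c("A", "B", "C", "D"))) {
    stop("subexperiment_cycle labels must be in {A, B, C, D}")
  }
  if (!setequal(subexperiment_cycle, c("A", "B", "C", "D"))) {
    stop("subexperiment_cycle must use all four labels A-D")
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      n_points = as.integer(n_points),
      n_averages = as.integer(n_averages),
      te = te,
      tr = tr,
      field_strength = field_strength,
      larmor_per_ppm = larmor_per_ppm,
      tx_ppm = tx_ppm,
      subexperiment_cycle = subexperiment_cycle
    ),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> %g Hz bandwidth, %d points, %d averages (cycle %s)\n",
    x$sampling_rate, x$n_points, x$n_averages,
    paste(x$subexperiment_cycle, collapse = "")
  ))
  cat(sprintf(
    "  TE/TR = %g/%g ms, %g T (%.3f Hz/ppm), transmitter at %g ppm\n",
    1000 * x$te, 1000 * x$tr, x$field_strength, x$larmor_per_ppm, x$tx_ppm
  ))
  invisible(x)
}

#' Time axis of one FID
#'
#' @param acq An \code{acq_params} object.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
time_axis <- function(acq) {
  (seq_len(acq$n_points) - 1) / acq$sampling_rate
}

#' Chemical-shift axis of a spectrum
#'
#' Frequencies are referenced to the transmitter: an offset of \code{f} Hz
#' maps to \code{tx_ppm + f / larmor_per_ppm}. The axis is stored ascending
#' in ppm (display convention in plots runs high-to-low ppm); the centre bin
#' (index \code{n_points/2 + 1} after standard fftshift reordering) sits
#' exactly at \code{tx_ppm}. Bin spacing is
#' \code{sampling_rate / (n_points * larmor_per_ppm)} ppm.
#'
#' @param acq An \code{acq_params} object.
#' @return Numeric vector of length \code{n_points}, strictly increasing.
#' @export
ppm_axis <- function(acq) {
  n <- acq$n_points
  f <- (seq_len(n) - 1 - n / 2) * acq$sampling_rate / n
  acq$tx_ppm + f / acq$larmor_per_ppm
}

#' Convert between Hz offsets and ppm
#'
#' @param hz,ppm Values to convert. \code{hz} is the frequency offset from
#'   the transmitter; \code{ppm} an absolute chemical shift.
#' @param acq An \code{acq_params} object.
#' @return The converted value.
#' @export
hz_to_ppm <- function(hz, acq) acq$tx_ppm + hz / acq$larmor_per_ppm

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(ppm, acq) (ppm - acq$tx_ppm) * acq$larmor_per_ppm
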