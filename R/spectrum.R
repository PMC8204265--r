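#' Complex frequency-domain spectrum with a ppm axis
#'
#' Lightweight container pairing complex spectral values with their
#' chemical-shift axis. The axis is stored ascending in ppm.
#'
#' @param values Complex vector of spectral values.
#' @param ppm Numeric vector, same length, strictly increasing.
#' @param larmor_per_ppm Hz per ppm, kept so linewidths can be reported in Hz.
#' @param provenance Free-text label, e.g. \code{"DIFF_GABA"} or \code{"SUM"}.
#' @return An object of class \code{mrs_spectrum}.
#' @export
mrs_spectrum <- function(values, ppm, larmor_per_ppm, provenance = "") {
  stopifnot(length(values) == length(ppm), all(diff(ppm) > 0),
            larmor_per_ppm > 0)
  structure(
    list(values = as.complex(values), ppm = as.numeric(ppm),
         larmor_per_ppm = larmor_per_ppm, provenance = provenance),
    class = "mrs_spectrum"
  )
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum%s> %d points, %.2f to %.2f ppm\n",
              if (nzchar(x$provenance)) paste0(" ", x$provenance) else "",
              length(x$values), min(x$ppm), max(x$ppm)))
  invisible(x)
}

# Reorder unnormalized DFT output so signed frequencies run ascending
# (negative first), matching the ascending ppm axis.
fftshift <- function(x) {
  n <- length(x)
  c(x[(n / 2 + 1):n], x[1:(n / 2)])
}

#' Fourier transform an FID into a spectrum
#'
#' Applies the unnormalized forward discrete Fourier transform and reorders
#' the bins so they align with [ppm_axis()]. With this normalization the sum
#' of |FID|^2 equals the mean of |spectrum|^2 (Parseval); every quantitative
#' output of the pipeline is a ratio and therefore independent of the
#' normalization choice. A time-domain component
#' \code{exp(2i * pi * f * t)} lands at chemical shift
#' \code{tx_ppm + f / larmor_per_ppm}.
#'
#' @param fid Complex vector of length \code{acq$n_points}.
#' @param acq An \code{acq_params} object.
#' @param provenance Optional label stored on the spectrum.
#' @return An [mrs_spectrum()].
#' @export
fid_to_spectrum <- function(fid, acq, provenance = "") {
  if (length(fid) != acq$n_points) {
    stop(sprintf("FID has %d samples but acq expects %d",
                 length(fid), acq$n_points))
  }
  if (any(!is.finite(Re(fid))) || any(!is.finite(Im(fid)))) {
    stop("FID contains non-finite samples")
  }
  # With fft()'s exp(-2*pi*i*j*k/n) kernel a +f Hz sinusoid lands at bin
  # f/df, i.e. at tx_ppm + f/larmor_per_ppm on the ascending ppm axis.
  vals <- fftshift(stats::fft(as.complex(fid)))
  mrs_spectrum(vals, ppm_axis(acq), acq$larmor_per_ppm, provenance)
}

#' Restrict a spectrum to a ppm window
#'
#' @param spec An [mrs_spectrum()].
#' @param window Numeric length-2, ppm bounds (any order).
#' @return An [mrs_spectrum()] over the window.
#' @export
crop_spectrum <- function(spec, window) {
  lo <- min(window); hi <- max(window)
  keep <- spec$ppm >= lo & spec$ppm <= hi
  if (!any(keep)) stop("window outside the spectrum's ppm axis")
  mrs_spectrum(spec$values[keep], spec$ppm[keep], spec$larmor_per_ppm,
               spec$provenance)
}
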