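#' Hadamard combination of the four editing sub-experiments
#'
#' With A-D the mean spectra of the four sub-experiments, forms
#' \describe{
#'   \item{diff_gaba}{(A + B - C - D) / 4 — isolates resonances edited by
#'     the 1.9 ppm pulse (GABA+ and co-edited Glx)}
#'   \item{diff_gsh}{(A - B + C - D) / 4 — isolates the 4.56 ppm-edited GSH}
#'   \item{sum}{(A + B + C + D) / 4 — all resonances, used for the
#'     non-edited reference peaks (NAA, Cr, Cho)}
#'   \item{off}{D — the fully edit-off sub-experiment}
#' }
#' The /4 scaling means a fully modulated unit resonance appears with unit
#' amplitude in its difference spectrum; every quantitative output of the
#' pipeline is a ratio, so any consistent scale would do.
#'
#' @param ds A [hermes_dataset()] (normally preprocessed).
#' @return An object of class \code{combined_spectra}: list of
#'   [mrs_spectrum()] \code{diff_gaba}, \code{diff_gsh}, \code{sum},
#'   \code{off}, plus \code{water} (mean water-reference spectrum) and
#'   \code{n_averages_used}.
#' @export
hadamard_combine <- function(ds) {
  counts <- table(factor(ds$subexperiment, levels = c("A", "B", "C", "D")))
  if (length(unique(as.integer(counts))) != 1L || any(counts == 0)) {
    stop("sub-experiments must be balanced and all present")
  }
  mean_spec <- function(rows) {
    fid <- colMeans(ds$fids[rows, , drop = FALSE])
    fid_to_spectrum(fid, ds$acq)$values
  }
  sa <- mean_spec(which(ds$subexperiment == "A"))
  sb <- mean_spec(which(ds$subexperiment == "B"))
  sc <- mean_spec(which(ds$subexperiment == "C"))
  sd_ <- mean_spec(which(ds$subexperiment == "D"))
  ppm <- ppm_axis(ds$acq)
  lpp <- ds$acq$larmor_per_ppm
  water <- fid_to_spectrum(colMeans(ds$water), ds$acq, "WATER")
  structure(
    list(
      diff_gaba = mrs_spectrum((sa + sb - sc - sd_) / 4, ppm, lpp,
                               "DIFF_GABA"),
      diff_gsh = mrs_spectrum((sa - sb + sc - sd_) / 4, ppm, lpp,
                              "DIFF_GSH"),
      sum = mrs_spectrum((sa + sb + sc + sd_) / 4, ppm, lpp, "SUM"),
      off = mrs_spectrum(sd_, ppm, lpp, "OFF"),
      water = water,
      n_averages_used = nrow(ds$fids)
    ),
    class = "combined_spectra"
  )
}

#' @export
print.combined_spectra <- function(x, ...) {
  cat(sprintf("<combined_spectra> %d averages: DIFF_GABA, DIFF_GSH, SUM, OFF\n",
              x$n_averages_used))
  invisible(x)
}

#' Cumulative-averaging subsets
#'
#' Emulates shorter scan durations by truncating the acquisition: subset k
#' holds the first \code{start + (k-1) * step} averages in acquisition
#' order, preserving the A-D balance. The default grid 80, 100, ..., 320
#' yields 13 subsets.
#'
#' @param ds A [hermes_dataset()].
#' @param start,stop,step Grid of averages; \code{start} and \code{step}
#'   must be divisible by 4, \code{stop} defaults to all averages.
#' @return Named list of [hermes_dataset()] objects (names are the NA
#'   counts).
#' @export
cumulative_subsets <- function(ds, start = 80, stop = NULL, step = 20) {
  if (is.null(stop)) stop <- nrow(ds$fids)
  if (stop > nrow(ds$fids)) stop("stop exceeds the available averages")
  if (start %% 4L != 0L || step %% 4L != 0L) {
    stop("start and step must be divisible by 4")
  }
  grid <- seq(start, stop, by = step)
  out <- lapply(grid, function(n) head_averages(ds, n))
  names(out) <- as.character(grid)
  out
}

#' Export combined spectra to CSV
#'
#' Writes one row per spectral point with columns ppm and the real and
#' imaginary parts of each combination.
#'
#' @param cs A [hadamard_combine()] result.
#' @param file Output CSV path.
#' @return \code{file}, invisibly.
#' @export
write_combined_csv <- function(cs, file) {
  df <- data.frame(ppm = cs$sum$ppm)
  for (nm in c("diff_gaba", "diff_gsh", "sum", "off")) {
    df[[paste0(nm, "_re")]] <- Re(cs[[nm]]$values)
    df[[paste0(nm, "_im")]] <- Im(cs[[nm]]$values)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
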