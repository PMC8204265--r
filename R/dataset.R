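#' Tissue fractions of the MRS voxel
#'
#' Grey-matter, white-matter and CSF volume fractions of the voxel, as
#' delivered by an anatomical segmentation pipeline. Fractions must sum to 1.
#'
#' @param f_gm,f_wm,f_csf Fractions in \[0, 1\].
#' @return An object of class \code{tissue_fractions}.
#' @export
tissue_fractions <- function(f_gm, f_wm, f_csf) {
  f <- c(f_gm, f_wm, f_csf)
  stopifnot(all(is.finite(f)), all(f >= 0), all(f <= 1))
  if (abs(sum(f) - 1) > 1e-6) stop("tissue fractions must sum to 1")
  structure(list(f_gm = f_gm, f_wm = f_wm, f_csf = f_csf),
            class = "tissue_fractions")
}

#' A single-voxel HERMES dataset
#'
#' Holds every transient of one acquisition as rows of a complex matrix,
#' labelled by editing sub-experiment, together with at least one
#' unsuppressed-water reference FID and the acquisition metadata. Row order
#' is acquisition order.
#'
#' @param acq An [acq_params()].
#' @param fids Complex matrix, \code{n_averages} rows by \code{n_points}
#'   columns; one FID per row.
#' @param subexperiment Character vector of labels in \code{A}-\code{D},
#'   one per row of \code{fids}; counts must be balanced.
#' @param water Complex matrix of water-reference FIDs (>= 1 row).
#' @param subject_id Identifier string.
#' @param region One of \code{"ACC"}, \code{"thalamus"}, \code{"other"}.
#' @param tissue Optional [tissue_fractions()].
#' @return An object of class \code{hermes_dataset}.
#' @export
hermes_dataset <- function(acq, fids, subexperiment, water,
                           subject_id = "sim", region = "other",
                           tissue = NULL) {
  stopifnot(inherits(acq, "acq_params"), is.matrix(fids), is.matrix(water))
  if (ncol(fids) != acq$n_points || ncol(water) != acq$n_points) {
    stop("FID matrices must have acq$n_points columns")
  }
  if (nrow(fids) != length(subexperiment)) {
    stop("one sub-experiment label is required per FID row")
  }
  bad <- setdiff(unique(subexperiment), c("A", "B", "C", "D"))
  if (length(bad)) {
    stop(sprintf("unknown sub-experiment label(s): %s",
                 paste(bad, collapse = ", ")))
  }
  counts <- table(factor(subexperiment, levels = c("A", "B", "C", "D")))
  if (length(unique(as.integer(counts))) != 1L) {
    stop("sub-experiment counts must be equal (balanced A-D)")
  }
  if (!region %in% c("ACC", "thalamus", "other")) {
    stop("region must be one of ACC, thalamus, other")
  }
  if (!is.null(tissue)) stopifnot(inherits(tissue, "tissue_fractions"))
  structure(
    list(acq = acq, fids = fids, subexperiment = as.character(subexperiment),
         water = water, subject_id = subject_id, region = region,
         tissue = tissue),
    class = "hermes_dataset"
  )
}

#' @export
print.hermes_dataset <- function(x, ...) {
  cat(sprintf(
    "<hermes_dataset> subject %s, region %s: %d averages x %d points, %d water ref(s)\n",
    x$subject_id, x$region, nrow(x$fids), ncol(x$fids), nrow(x$water)))
  invisible(x)
}

#' Number of averages in a dataset
#' @param ds A [hermes_dataset()].
#' @return Integer count of transients.
#' @export
n_averages <- function(ds) nrow(ds$fids)

#' Keep the first n averages (acquisition order)
#'
#' Used to emulate shorter scan durations. \code{n} must preserve the A-D
#' balance, i.e. be divisible by four under the default interleaved cycle.
#'
#' @param ds A [hermes_dataset()].
#' @param n Number of leading averages to keep.
#' @return A [hermes_dataset()] with \code{n} averages.
#' @export
head_averages <- function(ds, n) {
  if (n > nrow(ds$fids)) stop("n exceeds the available averages")
  sub <- ds$subexperiment[seq_len(n)]
  counts <- table(factor(sub, levels = c("A", "B", "C", "D")))
  if (length(unique(as.integer(counts))) != 1L) {
    stop("subset breaks the A-D balance; choose n divisible by the cycle")
  }
  out <- ds
  out$fids <- ds$fids[seq_len(n), , drop = FALSE]
  out$subexperiment <- sub
  out
}
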