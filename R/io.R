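#' Read and write HERMES dataset bundles
#'
#' A bundle is a directory holding one acquisition in plain text:
#' \describe{
#'   \item{header.json}{acquisition parameters, subject/region metadata and
#'     the per-row sub-experiment labels}
#'   \item{fids.csv}{one row per average, \code{2 * n_points} columns of
#'     interleaved real,imag samples (no header row)}
#'   \item{water.csv}{same layout for the unsuppressed-water reference(s)}
#'   \item{tissue.json}{optional GM/WM/CSF fractions}
#' }
#' Samples are stored as decimal text at full double precision, so a
#' save/load round trip reproduces the dataset bit-exactly.
#'
#' @param ds A [hermes_dataset()].
#' @param path Bundle directory (created if missing).
#' @return \code{save_bundle} returns \code{path} invisibly;
#'   \code{load_bundle} returns a [hermes_dataset()].
#' @export
save_bundle <- function(ds, path) {
  stopifnot(inherits(ds, "hermes_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    sampling_rate = ds$acq$sampling_rate,
    n_points = ds$acq$n_points,
    n_averages = nrow(ds$fids),
    te = ds$acq$te, tr = ds$acq$tr,
    field_strength = ds$acq$field_strength,
    larmor_per_ppm = ds$acq$larmor_per_ppm,
    tx_ppm = ds$acq$tx_ppm,
    subexperiment_cycle = ds$acq$subexperiment_cycle,
    subexperiment = ds$subexperiment,
    subject_id = ds$subject_id,
    region = ds$region
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  write_cplx_csv(ds$fids, file.path(path, "fids.csv"))
  write_cplx_csv(ds$water, file.path(path, "water.csv"))
  if (!is.null(ds$tissue)) {
    jsonlite::write_json(unclass(ds$tissue), file.path(path, "tissue.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  hdr_file <- file.path(path, "header.json")
  if (!file.exists(hdr_file)) stop(sprintf("missing header: %s", hdr_file))
  hdr <- jsonlite::read_json(hdr_file, simplifyVector = TRUE)
  acq <- acq_params(
    sampling_rate = hdr$sampling_rate, n_points = hdr$n_points,
    n_averages = hdr$n_averages, te = hdr$te, tr = hdr$tr,
    field_strength = hdr$field_strength,
    larmor_per_ppm = hdr$larmor_per_ppm, tx_ppm = hdr$tx_ppm,
    subexperiment_cycle = hdr$subexperiment_cycle
  )
  fids <- read_cplx_csv(file.path(path, "fids.csv"), acq$n_points)
  water <- read_cplx_csv(file.path(path, "water.csv"), acq$n_points)
  if (nrow(fids) != hdr$n_averages) {
    stop(sprintf("fids.csv has %d rows but header declares n_averages = %d",
                 nrow(fids), hdr$n_averages))
  }
  if (length(hdr$subexperiment) != nrow(fids)) {
    stop("header sub-experiment labels do not match the FID row count")
  }
  tissue <- NULL
  tfile <- file.path(path, "tissue.json")
  if (file.exists(tfile)) {
    tj <- jsonlite::read_json(tfile, simplifyVector = TRUE)
    tissue <- tissue_fractions(tj$f_gm, tj$f_wm, tj$f_csf)
  }
  hermes_dataset(acq, fids, hdr$subexperiment, water,
                 subject_id = hdr$subject_id, region = hdr$region,
                 tissue = tissue)
}

# interleaved real,imag columns; full double precision, no header row
write_cplx_csv <- function(m, file) {
  out <- matrix(0, nrow(m), 2L * ncol(m))
  out[, seq(1L, 2L * ncol(m), by = 2L)] <- Re(m)
  out[, seq(2L, 2L * ncol(m), by = 2L)] <- Im(m)
  utils::write.table(format(out, digits = 17, scientific = TRUE, trim = TRUE),
                     file, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_cplx_csv <- function(file, n_points) {
  if (!file.exists(file)) stop(sprintf("missing matrix file: %s", file))
  m <- as.matrix(utils::read.table(file, sep = ",", header = FALSE))
  if (ncol(m) != 2L * n_points) {
    stop(sprintf("%s: expected %d columns (2 x n_points), found %d",
                 basename(file), 2L * n_points, ncol(m)))
  }
  re <- m[, seq(1L, ncol(m), by = 2L), drop = FALSE]
  im <- m[, seq(2L, ncol(m), by = 2L), drop = FALSE]
  matrix(complex(real = re, imaginary = im), nrow(m), n_points)
}
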