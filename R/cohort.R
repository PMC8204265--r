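#' Fit all metabolites and references on one reconstruction
#'
#' Runs the standard fit battery on a [hadamard_combine()] result: GABA+
#' single and double Gaussian plus Glx on the GABA difference spectrum, GSH
#' on the GSH difference spectrum, NAA/Cr/Cho Lorentzians on the SUM
#' spectrum, and the unsuppressed water Lorentzian. Noise is estimated per
#' spectrum in the signal-free 8.5-10.5 ppm region.
#'
#' @param cs A [hadamard_combine()] result.
#' @return Named list of \code{fit_result} objects (\code{gaba_sg},
#'   \code{gaba_dg}, \code{glx}, \code{gsh}, \code{naa}, \code{cr},
#'   \code{cho}, \code{water}) with an attribute \code{noise} holding the
#'   per-spectrum noise SDs.
#' @export
fit_battery <- function(cs) {
  noise <- c(diff_gaba = estimate_noise_sd(cs$diff_gaba),
             diff_gsh = estimate_noise_sd(cs$diff_gsh),
             sum = estimate_noise_sd(cs$sum))
  fits <- list(
    gaba_sg = fit_peak_model(cs$diff_gaba, "gaba_sg", noise[["diff_gaba"]]),
    gaba_dg = fit_peak_model(cs$diff_gaba, "gaba_dg", noise[["diff_gaba"]]),
    glx = fit_peak_model(cs$diff_gaba, "glx", noise[["diff_gaba"]]),
    gsh = fit_peak_model(cs$diff_gsh, "gsh", noise[["diff_gsh"]]),
    naa = fit_reference(cs$sum, "naa", noise[["sum"]]),
    cr = fit_reference(cs$sum, "cr", noise[["sum"]]),
    cho = fit_reference(cs$sum, "cho", noise[["sum"]]),
    water = fit_reference(cs$water, "water")
  )
  attr(fits, "noise") <- noise
  fits
}

fit_row <- function(subject, region, metabolite, model, n_avg, f) {
  tibble::tibble(
    subject = subject, region = region, metabolite = metabolite,
    model = model, n_averages = n_avg,
    integral = f$integral, fit_error_pct = f$fit_error_pct, snr = f$snr,
    fwhm_hz = f$fwhm_hz, converged = f$converged
  )
}

#' Cumulative-averaging duration curves
#'
#' For every dataset: preprocess once, then for each cumulative subset of
#' the grid reconstruct and fit GABA+ (double Gaussian), Glx and GSH,
#' recording the ratio to total creatine, SNR and fit error. This emulates
#' re-running the analysis at increasing scan duration.
#'
#' @param datasets List of [hermes_dataset()].
#' @param start,step Cumulative grid (see [cumulative_subsets()]).
#' @param lb_hz Line broadening passed to [preprocess_dataset()].
#' @param preprocess Set FALSE if datasets are already preprocessed.
#' @return A tibble with one row per subject x metabolite x NA:
#'   \code{subject}, \code{region}, \code{metabolite}, \code{n_averages},
#'   \code{ratio_to_cr}, \code{snr}, \code{fit_error_pct}.
#' @export
duration_curves <- function(datasets, start = 80, step = 20, lb_hz = 3,
                            preprocess = TRUE) {
  rows <- list()
  for (ds in datasets) {
    if (preprocess) ds <- preprocess_dataset(ds, lb_hz = lb_hz)$dataset
    for (sub in cumulative_subsets(ds, start = start, step = step)) {
      cs <- hadamard_combine(sub)
      noise_gaba <- estimate_noise_sd(cs$diff_gaba)
      noise_gsh <- estimate_noise_sd(cs$diff_gsh)
      cr <- fit_reference(cs$sum, "cr")
      fits <- list(
        gaba = fit_peak_model(cs$diff_gaba, "gaba_dg", noise_gaba),
        glx = fit_peak_model(cs$diff_gaba, "glx", noise_gaba),
        gsh = fit_peak_model(cs$diff_gsh, "gsh", noise_gsh)
      )
      for (m in names(fits)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = ds$subject_id, region = ds$region, metabolite = m,
          n_averages = nrow(sub$fids),
          ratio_to_cr = ratio_to_cr(fits[[m]], cr),
          snr = fits[[m]]$snr, fit_error_pct = fits[[m]]$fit_error_pct)
      }
    }
  }
  do.call(rbind, rows)
}

#' Square-root-of-averages regression
#'
#' Regresses the group-mean metric on \code{sqrt(NA)} (for SNR) or
#' \code{1 / sqrt(NA)} (for fit error) through the origin, reflecting the
#' expected scaling of signal averaging. \code{r_squared} is the squared
#' Pearson correlation between the group means and the transformed NA.
#'
#' @param table A [duration_curves()] tibble (one metabolite; filter first).
#' @param metric \code{"snr"} or \code{"fit_error"}.
#' @return List with \code{coefficient}, \code{r_squared} and the
#'   group-mean table used.
#' @export
sqrt_na_fit <- function(table, metric = c("snr", "fit_error")) {
  metric <- match.arg(metric)
  col <- if (metric == "snr") "snr" else "fit_error_pct"
  nas <- sort(unique(table$n_averages))
  if (length(nas) < 3) stop("need >= 3 distinct NA values")
  y <- vapply(nas, function(n) mean(table[[col]][table$n_averages == n]),
              numeric(1))
  x <- if (metric == "snr") sqrt(nas) else 1 / sqrt(nas)
  if (stats::sd(y) == 0) stop("metric is constant across NA (degenerate)")
  coef <- sum(x * y) / sum(x * x)
  list(coefficient = coef, r_squared = stats::cor(x, y)^2,
       means = tibble::tibble(n_averages = nas, metric = y))
}

#' Group-level summary statistics
#'
#' @param values Numeric vector, n >= 2.
#' @return List with \code{mean}, \code{sd} (sample SD), \code{sem}
#'   (SD / sqrt(n)), \code{cv_pct} (100 SD / mean) and \code{n}.
#' @export
group_stats <- function(values) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s, sem = s / sqrt(n), cv_pct = 100 * s / m, n = n)
}

#' Welch two-sample comparison of regions
#'
#' Unpaired Welch t-test (unequal variances), two-sided. Two identical
#' zero-variance groups return t = 0, p = 1 by convention.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @return List with \code{t_stat}, \code{p_value}, \code{df},
#'   \code{n_a}, \code{n_b}.
#' @export
compare_regions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(list(t_stat = 0, p_value = 1,
                df = length(a) + length(b) - 2,
                n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_a = length(a), n_b = length(b))
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, reconstruct, fit, quantify and cohort statistics
#' over a set of datasets, writing tidy CSV tables and a JSON summary.
#' Outputs in \code{out_dir}: \code{offsets.csv} (per-average registration
#' offsets and the per-subject drift metric), \code{fits.csv} (all fit
#' metrics), \code{quant.csv} (creatine ratios and water-referenced
#' concentrations, uncorrected and tissue-corrected), \code{duration.csv}
#' (cumulative-averaging table), and \code{summary.json} (group statistics,
#' region comparisons and square-root-of-NA regressions).
#'
#' @param datasets List of [hermes_dataset()] (e.g. from
#'   [simulate_cohort()] or [load_bundle()]).
#' @param out_dir Output directory, created if needed.
#' @param cp A [correction_params()].
#' @param exclude Character vector of subject ids to drop before analysis.
#' @param lb_hz Line broadening in Hz.
#' @param duration Run the cumulative-averaging analysis? (slowest stage)
#' @return Invisibly, a list with all tables and the summary.
#' @export
run_pipeline <- function(datasets, out_dir, cp = correction_params(),
                         exclude = character(), lb_hz = 3,
                         duration = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- Filter(function(d) !(d$subject_id %in% exclude), datasets)
  if (!length(datasets)) stop("no datasets left after exclusions")

  offsets <- list(); fits <- list(); quant <- list()
  processed <- list()
  for (ds in datasets) {
    pp <- preprocess_dataset(ds, lb_hz = lb_hz)
    processed[[length(processed) + 1L]] <- pp$dataset
    offsets[[length(offsets) + 1L]] <- tibble::tibble(
      subject = ds$subject_id, region = ds$region,
      average = seq_along(pp$report$per_average_freq),
      freq_hz = pp$report$per_average_freq,
      phase_rad = pp$report$per_average_phase,
      delta_delta0_ppm = pp$report$delta_delta0)

    cs <- hadamard_combine(pp$dataset)
    fb <- fit_battery(cs)
    met_of <- c(gaba_sg = "gaba", gaba_dg = "gaba", glx = "glx", gsh = "gsh",
                naa = "naa", cr = "cr", cho = "cho", water = "water")
    for (m in names(fb)) {
      fits[[length(fits) + 1L]] <- fit_row(ds$subject_id, ds$region,
                                           met_of[[m]], m, nrow(ds$fids),
                                           fb[[m]])
    }
    for (m in c("gaba", "glx", "gsh")) {
      fr <- fb[[if (m == "gaba") "gaba_dg" else m]]
      has_tissue <- !is.null(ds$tissue)
      quant[[length(quant) + 1L]] <- tibble::tibble(
        subject = ds$subject_id, region = ds$region, metabolite = m,
        ratio_to_cr = ratio_to_cr(fr, fb$cr),
        conc_uncorrected = water_scaled(fr, fb$water, ds$tissue, cp, m,
                                        "uncorrected"),
        conc_corrected = if (has_tissue)
          water_scaled(fr, fb$water, ds$tissue, cp, m, "tissue_corrected")
        else NA_real_)
    }
  }
  offsets <- do.call(rbind, offsets)
  fits <- do.call(rbind, fits)
  quant <- do.call(rbind, quant)

  dur <- NULL
  sqrt_fits <- NULL
  if (duration) {
    dur <- duration_curves(processed, lb_hz = lb_hz, preprocess = FALSE)
    sqrt_fits <- list()
    for (m in unique(dur$metabolite)) {
      sub <- dur[dur$metabolite == m, ]
      for (metric in c("snr", "fit_error")) {
        fitm <- sqrt_na_fit(sub, metric)
        sqrt_fits[[paste(m, metric, sep = "_")]] <-
          list(coefficient = fitm$coefficient, r_squared = fitm$r_squared)
      }
    }
  }

  regions <- unique(quant$region)
  summary <- list(group_stats = list(), region_tests = list(),
                  sqrt_na = sqrt_fits)
  for (m in unique(quant$metabolite)) {
    for (r in regions) {
      v <- quant$conc_corrected[quant$metabolite == m & quant$region == r]
      v <- v[is.finite(v)]
      if (length(v) >= 2) {
        summary$group_stats[[paste(m, r, sep = "_")]] <- group_stats(v)
      }
    }
    if (length(regions) == 2) {
      for (mode in c("conc_uncorrected", "conc_corrected")) {
        va <- quant[[mode]][quant$metabolite == m &
                              quant$region == regions[1]]
        vb <- quant[[mode]][quant$metabolite == m &
                              quant$region == regions[2]]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        if (length(va) >= 2 && length(vb) >= 2) {
          summary$region_tests[[paste(m, mode, sep = "_")]] <-
            compare_regions(va, vb)
        }
      }
    }
  }

  utils::write.csv(offsets, file.path(out_dir, "offsets.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(quant, file.path(out_dir, "quant.csv"), row.names = FALSE)
  if (!is.null(dur)) {
    utils::write.csv(dur, file.path(out_dir, "duration.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(offsets = offsets, fits = fits, quant = quant,
                 duration = dur, summary = summary))
}
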