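#' Correction parameters for water-referenced quantification
#'
#' Bundles the compartmental water relaxation times and water content used
#' in tissue correction, adult metabolite relaxation times, the
#' neonate/adult water relaxation ratios used to interpolate metabolite
#' relaxation to the neonatal brain, editing efficiencies, and the sequence
#' timing. Compartment values are neonatal 3 T literature-style defaults;
#' metabolite values are adult 3 T literature-style defaults. Every value is
#' overridable.
#'
#' @param water_t1,water_t2 Named numeric (gm, wm, csf): water relaxation
#'   times in seconds per compartment.
#' @param water_content Named numeric (gm, wm, csf): relative water density
#'   per compartment (unitless).
#' @param pure_water_conc Concentration of pure water in mM (55510).
#' @param metab_t1_adult,metab_t2_adult Named numeric per metabolite: adult
#'   relaxation times in seconds.
#' @param t1_ratio,t2_ratio Neonate/adult water relaxation ratios used to
#'   scale adult metabolite values (defaults 1.12 and 1.44).
#' @param kappa Named numeric per metabolite: editing efficiency in (0, 1].
#' @param te,tr Echo and repetition time in seconds.
#' @return An object of class \code{correction_params}.
#' @export
correction_params <- function(
    water_t1 = c(gm = 2.08, wm = 2.90, csf = 4.30),
    water_t2 = c(gm = 0.130, wm = 0.250, csf = 1.50),
    water_content = c(gm = 0.86, wm = 0.90, csf = 1.00),
    pure_water_conc = 55510,
    metab_t1_adult = c(gaba = 1.31, glx = 1.23, gsh = 0.40),
    metab_t2_adult = c(gaba = 0.088, glx = 0.180, gsh = 0.120),
    t1_ratio = 1.12, t2_ratio = 1.44,
    kappa = c(gaba = 0.5, glx = 0.5, gsh = 0.5),
    te = 0.080, tr = 2.0) {
  stopifnot(all(water_t1 > 0), all(water_t2 > 0), all(water_content > 0),
            pure_water_conc > 0, all(metab_t1_adult > 0),
            all(metab_t2_adult > 0), t1_ratio > 0, t2_ratio > 0,
            all(kappa > 0), all(kappa <= 1), te > 0, tr > 0)
  structure(list(water_t1 = water_t1, water_t2 = water_t2,
                 water_content = water_content,
                 pure_water_conc = pure_water_conc,
                 metab_t1_adult = metab_t1_adult,
                 metab_t2_adult = metab_t2_adult,
                 t1_ratio = t1_ratio, t2_ratio = t2_ratio,
                 kappa = kappa, te = te, tr = tr),
            class = "correction_params")
}

#' Interpolate metabolite relaxation times to the neonatal brain
#'
#' Neonatal metabolite T1/T2 have not been measured; they are estimated by
#' scaling adult values with the water relaxation ratios of neonates to
#' adults: T1 by 1.12 and T2 by 1.44 (defaults of [correction_params()]).
#'
#' @param t1_adult,t2_adult Adult relaxation times in seconds, > 0.
#' @param cp A [correction_params()].
#' @return List with \code{t1} and \code{t2} in seconds.
#' @export
neonatal_relaxation <- function(t1_adult, t2_adult, cp = correction_params()) {
  if (t1_adult <= 0 || t2_adult <= 0) stop("relaxation times must be > 0")
  list(t1 = t1_adult * cp$t1_ratio, t2 = t2_adult * cp$t2_ratio)
}

# steady-state relaxation attenuation
relax_attenuation <- function(t1, t2, te, tr) {
  (1 - exp(-tr / t1)) * exp(-te / t2)
}

#' Metabolite ratio to total creatine
#'
#' @param metab,cr \code{fit_result} objects for the metabolite and the
#'   creatine reference.
#' @return \code{metab$integral / cr$integral}.
#' @export
ratio_to_cr <- function(metab, cr) {
  stopifnot(is.finite(metab$integral), is.finite(cr$integral))
  if (cr$integral <= 0) stop("creatine integral must be positive")
  metab$integral / cr$integral
}

#' Water-referenced concentration with tissue and relaxation correction
#'
#' Scales the metabolite integral by the unsuppressed-water integral and
#' corrects for compartmental water content and relaxation. With
#' \code{R(T1, T2) = (1 - exp(-TR/T1)) * exp(-TE/T2)} and water-density
#' weighted fractions \code{f'_x = f_x w_x / sum(f_y w_y)} over GM, WM and
#' CSF:
#'
#' \deqn{conc = (I_M / I_W) \frac{\sum_x f'_x \cdot [H_2O] \cdot
#'   R(T1w_x, T2w_x)}{(1 - f'_{CSF}) \cdot R(T1_M, T2_M) \cdot \kappa}}
#'
#' where the metabolite relaxation times come from [neonatal_relaxation()].
#' No GM/WM metabolite concentration ratio is assumed: the correction is
#' purely water-side, plus exclusion of the metabolite-free CSF volume.
#' \code{mode = "uncorrected"} reproduces a plain water-scaled estimate by
#' treating the voxel as a single GM compartment (\code{f'_GM = 1}).
#'
#' @param metab,water \code{fit_result} objects for the metabolite and the
#'   unsuppressed water reference.
#' @param tissue A [tissue_fractions()] (ignored when uncorrected).
#' @param cp A [correction_params()].
#' @param metabolite Name used to look up relaxation times and kappa.
#' @param mode \code{"tissue_corrected"} (default) or \code{"uncorrected"}.
#' @return Concentration in institutional units.
#' @export
water_scaled <- function(metab, water, tissue, cp = correction_params(),
                         metabolite = "gaba",
                         mode = c("tissue_corrected", "uncorrected")) {
  mode <- match.arg(mode)
  if (water$integral <= 0) stop("water integral must be positive")
  if (!metabolite %in% names(cp$metab_t1_adult)) {
    stop(sprintf("no relaxation defaults for metabolite '%s'", metabolite))
  }
  rel <- neonatal_relaxation(cp$metab_t1_adult[[metabolite]],
                             cp$metab_t2_adult[[metabolite]], cp)
  r_m <- relax_attenuation(rel$t1, rel$t2, cp$te, cp$tr)
  kap <- cp$kappa[[metabolite]]

  if (mode == "uncorrected") {
    fprime <- c(gm = 1, wm = 0, csf = 0)
  } else {
    stopifnot(inherits(tissue, "tissue_fractions"))
    f <- c(gm = tissue$f_gm, wm = tissue$f_wm, csf = tissue$f_csf)
    fw <- f * cp$water_content[names(f)]
    fprime <- fw / sum(fw)
    if (fprime[["csf"]] >= 1) stop("voxel contains no brain tissue")
  }
  r_w <- relax_attenuation(cp$water_t1, cp$water_t2, cp$te, cp$tr)
  water_side <- sum(fprime * cp$pure_water_conc * r_w[names(fprime)])
  (metab$integral / water$integral) * water_side /
    ((1 - fprime[["csf"]]) * r_m * kap)
}
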