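# hermesneo

Simulation, preprocessing, Hadamard reconstruction and quantification of
HERMES-edited magnetic resonance spectroscopy (MRS) for the neonatal
brain, written for spectroscopists and methods researchers who need a
tested, fully scriptable reference pipeline for multi-metabolite
J-difference editing — GABA+, Glx and GSH from a single acquisition — at
the low-SNR, high-motion operating point of unsedated newborn imaging.

## What it computes

HERMES interleaves four editing sub-experiments (editing pulses at
1.9 ppm, 4.56 ppm, both, neither). With sub-experiment mean spectra
Ā, B̄, C̄, D̄ the package reconstructs

    DIFF_GABA = (Ā + B̄ − C̄ − D̄) / 4     (GABA+ and co-edited Glx)
    DIFF_GSH  = (Ā − B̄ + C̄ − D̄) / 4     (GSH)
    SUM       = (Ā + B̄ + C̄ + D̄) / 4     (NAA, Cr, Cho references)

after per-transient preprocessing: Klose eddy-current correction,
time-domain spectral registration (frequency/phase least squares with a
drift report Δδ₀), and 3 Hz exponential line broadening. Peaks are fitted
by bounded least squares — single or shared-width double Gaussian for the
neonatal GABA+ 3 ppm pseudo-doublet, double Gaussian Glx, Gaussian GSH,
Lorentzian references — and quantified as ratios to total creatine and
against unsuppressed water with full compartmental tissue/relaxation
correction:

    c_M = (I_M / I_W) · Σ_x f'_x [H2O] R(T1w_x, T2w_x)
          ───────────────────────────────────────────────
          (1 − f'_CSF) · R(T1_M, T2_M) · κ

with R(T1,T2) = (1 − e^(−TR/T1)) e^(−TE/T2), water-density-weighted
fractions f'_x over GM/WM/CSF, metabolite relaxation interpolated to the
neonate by the water ratios T1 × 1.12 and T2 × 1.44, and editing
efficiency κ. A cohort layer adds the scan-duration analysis (cumulative
averages NA = 80…320), √NA regressions of SNR and fit error, group
statistics and Welch region comparisons. A seeded synthetic-data module
generates single datasets and cohorts with the editing structure, noise,
residual motion (~0.03 ppm frequency jitter) and region-dependent tissue
composition that the analysis assumes.

## Worked example

```r
library(hermesneo)
acq <- acq_params()    # 2 kHz, 2048 pts, 320 averages, TE/TR 80/2000 ms, 3 T
ds <- simulate_dataset(acq, seed = 101, subject_id = "demo", region = "ACC",
                       tissue = tissue_fractions(0.35, 0.45, 0.20))
pp <- preprocess_dataset(ds)          # ECC + registration + 3 Hz broadening
cs <- hadamard_combine(pp$dataset)    # DIFF_GABA / DIFF_GSH / SUM / OFF
fb <- fit_battery(cs)                 # all peak models + references

pp$report$delta_delta0                # drift metric
fb$gaba_dg                            # GABA+ double-Gaussian fit
ratio_to_cr(fb$gaba_dg, fb$cr)
water_scaled(fb$gaba_dg, fb$water, ds$tissue, metabolite = "gaba")
```

prints

```
drift metric: 0.0284 ppm
<fit_result> 2 component(s) at 2.950/3.067 ppm, integral 7.737, fit error 6.30%, SNR 8.7
GABA+/Cr: 0.0973
GABA+ (water-scaled): 92.5 i.u. uncorrected, 124.7 i.u. tissue-corrected
NAA linewidth: 9.0 Hz
```

i.e. the registration recovers the ~0.03 ppm injected motion scatter, the
edited GABA+ doublet is fitted with two components around 3 ppm at SNR
≈ 9 and ~6% fit error, the NAA linewidth sits at 9 Hz after broadening,
and tissue correction rescales the water-referenced value for the voxel's
20% CSF. Institutional units (i.u.) are water-scaled pseudo-concentrations
without absolute calibration.

The `analysis/` directory holds the narrative drivers:
`01_example_subject.R` (one dataset end to end),
`02_cohorts.R` (ACC n = 16 and thalamus n = 14 cohorts through the full
pipeline; tables under `results/`), `03_duration_study.R` (cumulative
averaging, √NA fits, group CV) and `04_region_comparison.R` (Welch tests
before/after tissue correction). Each is a plain `Rscript` run from the
repository root.

## Layout

- `R/` — acquisition/axis types, bundle I/O, simulator, preprocessing,
  Hadamard reconstruction, peak fitting, quantification, cohort analysis
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/hermes-neonatal-pipeline.Rmd` — the methods notes: model
  assumptions, parameter provenance, numerical choices, limitations
- `analysis/`, `scripts/`, `results/` — drivers, acceptance script, tables
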