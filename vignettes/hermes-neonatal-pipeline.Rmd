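---
title: "Edited MRS of the neonatal brain: the hermesneo pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edited MRS of the neonatal brain: the hermesneo pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

GABA, glutamate + glutamine (Glx) and glutathione (GSH) resonate underneath
much stronger signals (creatine, NAA, choline) in the in vivo proton
spectrum. J-difference editing solves this by acquiring interleaved
sub-experiments with a frequency-selective pulse alternately on and off a
coupled partner resonance and subtracting; HERMES (Hadamard-encoded
editing) runs **four** sub-experiments per cycle — editing pulses at
1.9 ppm (GABA), 4.56 ppm (GSH), both, or neither — so that linear
combinations of the four mean spectra isolate GABA+ and GSH simultaneously
with no SNR penalty over two separate two-condition experiments.

With sub-experiment mean spectra $\bar A \ldots \bar D$ the package forms

$$\mathrm{DIFF_{GABA}} = \tfrac14(\bar A + \bar B - \bar C - \bar D), \quad
  \mathrm{DIFF_{GSH}} = \tfrac14(\bar A - \bar B + \bar C - \bar D), \quad
  \mathrm{SUM} = \tfrac14(\bar A + \bar B + \bar C + \bar D).$$

The $1/4$ scale makes a fully modulated unit resonance appear with unit
amplitude; any consistent scale would do, since every quantitative output
is a ratio (asserted by a scale-invariance test).

Neonates add three specific difficulties that shape the pipeline:

1. **Low signal.** Metabolite levels are lower than in adults and the
   voxel smaller (15.625 mL for both prescriptions used here:
   31.25 × 25 × 20 mm³ anterior cingulate, 25³ mm³ thalamus), so the SNR
   budget and its growth with averaging matter.
2. **Motion.** Unsedated neonates move; even with scanner-side prospective
   frequency correction a residual per-average frequency/phase scatter of
   ~0.03 ppm remains and must be removed retrospectively, because editing
   subtraction turns small misalignments of the large creatine singlet
   into artifacts comparable to the whole GABA+ signal.
3. **The 3 ppm pseudo-doublet.** With low co-edited macromolecule (MM)
   contamination the edited GABA+ signal is a resolved doublet, so a
   single-Gaussian fit (the adult habit) underfits; the pipeline offers a
   shared-width double Gaussian alongside it.

## Signal model and simulator

Each resonance is a damped complex exponential,
$x(t) = \sum_k a_k\, m_k(e)\, \exp(2\pi i \nu_k t - t/\tau_k + i\varphi_k)$,
with $\nu_k = (\delta_k - \delta_{tx}) \cdot f_{\mathrm{Larmor}}$,
Lorentzian FWHM $\mathrm{lw}_k = 1/(\pi\tau_k)$, and an editing modulation
$m_k(e) \in [-1, 1]$ per sub-experiment. The modulation is a deliberate
simplification of J-evolution physics: the pipeline requires correct
Hadamard algebra and realistic lineshapes, not a density-matrix
simulation. Acquisition defaults are 2 kHz bandwidth, 2048 complex points,
320 averages cycling A–D, TE/TR = 80/2000 ms at 3 T, transmitter on
creatine at 3 ppm.

Key generator choices (all configurable, defaults frozen as the study
conditions):

* **GABA+ doublet**: two equal components at 3.00 ± half of 15 Hz; the
  splitting is shown but never quantified in the neonatal literature, so
  15 Hz (≈ 0.117 ppm at 3 T) is a configurable default. Neonate mode has
  MM amplitude 0 (resolved doublet); adult mode adds a broad 3 ppm MM
  component that fills the notch.
* **Amplitudes** are signal units proportional to concentration times an
  effective visibility. They were set once so the full-length (NA = 320)
  pipeline lands in the quality regime reported for neonatal HERMES:
  edited GABA+ SNR below 10, Glx roughly twice that, GSH in between,
  NAA linewidth ≈ 9 Hz after 3 Hz broadening. The cohort generator maps
  true concentrations (default GABA+ 0.16 mM, the neonatal
  anterior-cingulate scale) linearly onto these amplitudes.
* **Noise and instability**: complex white noise (SD 4.0 signal units per
  component per point); per-average frequency offsets are a linear drift
  (0.001 ppm/min) plus Gaussian jitter (SD 0.0375 ppm) and phase jitter
  (SD 0.2 rad). The jitter SD was chosen so the mean absolute offset is
  ≈ 0.03 ppm — the residual-motion scale reported for unsedated neonates —
  via $E|N(0,s)| = s\sqrt{2/\pi}$.
* **Tissue coupling**: per-subject GM/WM/CSF fractions are drawn around
  region defaults (ACC 0.35/0.45/0.20; thalamus 0.75/0.23/0.02 — invented
  to qualitatively match the segmentation contrast between the two
  voxels, which is published only graphically). Metabolite signal scales
  with the water-density-weighted brain-tissue volume
  $f_{GM}w_{GM} + f_{WM}w_{WM}$ (metabolites are absent from CSF) and the
  unsuppressed-water reference with
  $\sum_x f_x w_x R(T1^w_x, T2^w_x)$, both normalized to a fixed
  region-independent reference composition (0.5/0.4/0.1). This is what
  makes tissue correction meaningful on simulated cohorts: it removes
  exactly the variance this coupling injects.

What the generator does **not** emulate: J-evolution and multiplet
structure beyond the ±1 modulation; lineshape heterogeneity (all lines are
Lorentzian, so fitted singlet SNR runs higher than in vivo); eddy-current
phase distortions (the correction is exercised with constructed
corruptions in tests); co-editing of NAA by the 1.9 ppm pulse (off by
default); water-suppression dynamics. Passing tests therefore demonstrate
the correctness of the algebra, alignment, fitting and correction stages
under realistic SNR and motion statistics — not robustness to every
artifact of real scanner data.

## Preprocessing

Order of operations: eddy-current correction → spectral registration →
3 Hz exponential line broadening. Apodization comes last so it cannot bias
the registration; the published pipelines list these steps without fixing
an order.

**Eddy-current correction** is Klose-style: the instantaneous phase of the
water reference is subtracted point by point. Because the transmitter sits
at 3 ppm, the water FID is first demodulated to the carrier (its dominant
frequency estimated from the spectrum) so that only instrumental phase is
removed, not a 1.68 ppm frequency shift. Zero-magnitude water samples have
undefined phase and are left untouched with a warning.

**Spectral registration** aligns each transient by time-domain least
squares: find $(f, \phi)$ minimizing
$\sum_n |x_m(t_n) e^{i(2\pi f t_n + \phi)} - r(t_n)|^2$ over the first
0.2 s of the FID (the tail is noise-dominated). For fixed $f$ the optimal
phase is analytic, so the search is one-dimensional: a 0.5 Hz coarse grid
over ±20 Hz, then golden-section refinement. Two design points deviate
from the obvious implementation, both motivated by editing:

* **Within sub-experiment first.** Averages are aligned to their own
  sub-experiment's reference (pointwise median on the first pass — robust
  to a single badly shifted transient — then the mean of the aligned
  data), so editing differences never enter the per-average estimates.
* **Frame harmonization on NAA.** The four sub-experiment frames are then
  reconciled by measuring each mean's residual offset on the non-edited
  NAA singlet: centre from a Lorentzian + linear-baseline fit, phase from
  the complex correlation over the NAA window. A broadband correlation is
  systematically pulled by tails of the edited resonances,
  while a fitted peak centre with a baseline term is locally immune; the
  creatine/choline region cannot be used at all because the GABA+ doublet
  lives inside it.

The offset report carries the estimated per-average offsets (the negatives
of the applied corrections) and the drift metric $\Delta\delta_0$, defined
here as the **mean absolute** estimated frequency offset in ppm (a maximum
variant is available); whether published values of this metric derive from the
prospective water log or retrospectively is not stated, so it is computed
retrospectively and documented.

## Fitting

All fits are bounded Levenberg–Marquardt least squares on the real part of
the spectrum with a linear baseline, deterministic given the documented
initialization (equal amplitudes at fixed initial centres, fixed initial
width, flat baseline at the window median). "Weighted least squares" is
realized as unit weights — spectral noise is homoscedastic across a fit
window. Component centres are reported ascending (the tie-break for the
symmetric double-Gaussian start at 3.00 ± 0.06 ppm). Non-convergence
returns the best iterate with `converged = FALSE` rather than failing.

Models and windows (windows follow common editing-analysis practice; none
are published for the reference pipeline): GABA+ single or shared-width
double Gaussian over 2.79–3.55 ppm; Glx shared-width double Gaussian at
3.71/3.79 ppm over 3.45–4.10 ppm; GSH single Gaussian at 2.95 ppm over
2.75–3.15 ppm (no functional form is published for the standard GSH-editing fit, so a
single Gaussian + linear baseline stands in; GABA+ and Glx are fitted in
separate windows for the same reason). References are Lorentzians: NAA
over 1.8–2.2 ppm and water over 4.2–5.2 ppm alone; creatine and choline
jointly as a double Lorentzian over 2.8–3.4 ppm, because they sit 0.17 ppm
apart and a single-Lorentzian window cannot avoid the neighbour.

Derived metrics, since the field's definitions vary: **fit error** =
100 × residual SD / fitted baseline-removed peak height; **SNR** = peak
height / (2 × noise SD), noise estimated in 8.5–10.5 ppm after a
second-order polynomial detrend; **linewidth** = Lorentzian FWHM (2γ) or
Gaussian $2\sqrt{2\ln 2}\,\sigma$, in Hz; **integral** = analytic area
($a\sigma\sqrt{2\pi}$ per Gaussian, $\pi a \gamma$ per Lorentzian).

## Quantification

Metabolites are referenced to total creatine (ratio of integrals) and to
unsuppressed water with full compartmental correction:

$$c_M = \frac{I_M}{I_W} \cdot
  \frac{\sum_{x \in \{GM,WM,CSF\}} f'_x \,[\mathrm{H_2O}]\, R(T1^w_x, T2^w_x)}
       {(1 - f'_{CSF})\, R(T1_M, T2_M)\, \kappa},
  \qquad R(T1,T2) = (1 - e^{-TR/T1})\,e^{-TE/T2},$$

with water-density-weighted fractions $f'_x = f_x w_x / \sum_y f_y w_y$.
No GM/WM metabolite concentration ratio is assumed (no α-correction): the
correction is purely water-side plus exclusion of metabolite-free CSF.
Metabolite relaxation times are interpolated from adult values by the
neonate/adult **water** relaxation ratios — T1 × 1.12, T2 × 1.44 — because
neonatal metabolite relaxation has not been measured. Compartment water
values are neonatal literature-style defaults and every number is
overridable through `correction_params()`. Editing efficiency κ defaults
to 0.5 per edited metabolite (never published for this protocol;
configurable). The "uncorrected" mode, used as the before-correction axis,
treats the voxel as a single GM compartment — one reasonable reading of a
convention the field leaves undefined. Concentrations are
institutional units; no absolute-mM claim is made, and truth-recovery
tests use proportionality only.

## Cohort analysis

The scan-duration study truncates each (preprocessed) acquisition to the
first 80, 100, …, 320 averages in acquisition order — 13 subsets;
arithmetic gives 13 subsets even though such grids are often described as twelve, and
none is dropped silently — preserving A–D balance, then reconstructs and
fits each subset. Group-mean SNR is regressed on $\sqrt{NA}$ and fit error
on $1/\sqrt{NA}$, through the origin, with $R^2$ the squared Pearson
correlation on group means (matching how such curves are plotted, rather
than pooling subjects). Region comparisons use Welch's unpaired t-test
(the reference says only "unpaired"; Welch is the safer default and the
choice is documented), two-sided, no multiple-testing correction (raw p
thresholds are the field's reporting habit here). Group summaries are
mean, sample SD, SEM, and CV% = 100·SD/mean. Exclusions are config-driven
lists, never automatic.

## Problem sizes and runtime choices

The test-suite and acceptance problem sizes are the package's own
choices: 16 simulated datasets for the cumulative-averaging study (the
anterior-cingulate group size of a realistic neonatal cohort; group
means from 10 leave the weakest $R^2$ — Glx fit error, which varies
little over NA — straddling its bound out of pure sampling noise), 50
seeds for the double-vs-single-Gaussian comparison, 20 seeds for CV and
drift-recovery properties, and 6 subjects per point for the five-point
concentration sweep. Mechanism-isolating properties (CV reduction by
tissue correction) run noiseless with fixed true concentrations so the
inequality is deterministic rather than a coin flip against fit noise.

## Known limitations

* Editing modulation is binary; transition-band effects of the 20 ms
  editing pulses (partial co-editing, κ < 1 structure) are summarized by a
  single κ.
* GSH fit quality is optimistic relative to in vivo reports, where
  overlap and subtraction artifacts inflate GSH fit error several-fold;
  consequently the weak in vivo relationship of GSH fit error with
  $1/\sqrt{NA}$ appears strong on simulated data.
* The Lorentzian-only lineshape makes singlet SNR higher than in vivo at
  matched edited-metabolite SNR.
* Bundle I/O is plain text (JSON + CSV) by design; vendor raw formats and
  NIfTI-MRS are out of scope.
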