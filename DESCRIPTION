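Package: hermesneo
Title: HERMES Edited MRS Simulation, Reconstruction and Quantification for
    the Neonatal Brain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for Hadamard-encoded (HERMES) J-difference edited
    magnetic resonance spectroscopy of the neonatal brain. Simulates
    four-sub-experiment edited free induction decays with realistic noise
    and frequency/phase instability, preprocesses averages (line
    broadening, eddy-current correction, time-domain spectral
    registration), reconstructs GABA+/Glx and GSH difference spectra by
    Hadamard combination, fits single- and double-Gaussian peak models,
    and quantifies metabolites against total creatine and unsuppressed
    water with full compartmental (GM/WM/CSF) tissue and neonatal
    relaxation correction. Includes a cumulative-averaging analysis of
    SNR, fit error and group-level coefficient of variation as a function
    of the number of averages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
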