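Package: radstab
Title: Radiation-Stability Assessment of Solid Drugs by NMR Relaxometry,
    EPR, FT-IR, Colorimetry, HPLC and Thermal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the radiation stability of solid active
    pharmaceutical ingredients after electron-beam irradiation. Implements a
    multi-motion BPP/Woessner spin-lattice relaxation model with Arrhenius
    correlation times and weighted multi-start fitting over temperature,
    saturation-recovery T1 extraction, quantification of radiation-induced
    radicals from first-derivative EPR sweeps (baseline correction, smoothing,
    reference-line normalization, double integration, peak-to-peak linewidths,
    g-factors), FT-IR spectral conformity factors, CIE76 colour differences
    with a verbal classification scale, ICH-style HPLC validation statistics
    (linearity, RSD, LOD, LOQ, content versus standard), melting-point and DSC
    endotherm characterization, and seeded synthetic-data generators for every
    modality so the whole pipeline can be exercised and validated without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
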