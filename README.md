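# radstab

Radiation-stability assessment of solid drug substances, built around the
measurement battery used to qualify electron-beam sterilization of the
NSAIDs diclofenac and aceclofenac: solid-state ¹H-NMR relaxometry, EPR
radical quantification, FT-IR spectral conformity, CIELAB colorimetry,
ICH-style HPLC validation, and melting-point/DSC comparisons. The package is
aimed at analysts who need the *models and statistics* of such a study as
reusable, testable code — every input modality has a seeded synthetic-data
generator that returns its ground truth, so the whole pipeline runs and
validates without instrument files.

## The core model

Spin-lattice relaxation over temperature is described by additive BPP
spectral-density terms, one per thermally activated motion, with Arrhenius
correlation times:

$$\frac{1}{T_1}(T) = \sum_i C_i\left[\frac{\tau_i}{1+\omega_0^2\tau_i^2} +
\frac{4\tau_i}{1+4\omega_0^2\tau_i^2}\right],\qquad
\tau_i(T)=\tau_{0,i}e^{E_{a,i}/RT}.$$

A motion's rate contribution peaks where ω₀τ ≈ 0.6158, pinning the T₁
minimum; `fit_relaxation_model()` refits τ₀ and Eₐ (and optionally the
amplitudes Cᵢ) to a measured or simulated T₁(T) series by weighted
multi-start Levenberg–Marquardt in rate space. Around that core sit the
processing chains for the other modalities: baseline correction,
Savitzky–Golay smoothing, reference-line normalization and double
integration of derivative EPR sweeps; Pearson conformity factors between
FT-IR spectra; CIE76 ΔE with the verbal visibility scale; calibration
statistics with LOD = 3.3 Sy/a and LOQ = 10 Sy/a; DSC endotherm area with
linear baseline and tangent onset. `run_assessment()` strings all of it into
a per-dose verdict table. See `vignette("radiation-stability")` for the
model assumptions and design choices.

## Worked example

Calibrate the three-motion aceclofenac model so its T₁ minimum is 58 s,
simulate a 30-point temperature sweep at 5% noise, and refit it:

```r
library(radstab)

omega0 <- 2 * pi * 25e6                      # 25 MHz proton Larmor frequency
motions <- calibrate_amplitude(ac_reference_motions(), 58, omega0)
find_t1_minimum(motions, omega0)
#> T1 minimum: 58.0 s at 157.4 K

sim <- gen_relaxation_dataset(motions, seq(80, 345, length.out = 30),
                              noise_level = 0.05, seed = 42)
fit <- fit_relaxation_model(sim$dataset, n_motions = 3, n_starts = 32, seed = 42,
                            amplitudes = vapply(motions, `[[`, numeric(1), "amplitude"),
                            labels = c("whole_molecule", "ester_group", "proton_jump"))
fit
#> <relaxation_fit> converged, weighted RSS = 36.46, 44 starts
#> <motion_model> whole_molecule: tau0 = 6.72e-13 s, Ea = 0.798 kJ/mol, C = 5e+08 s^-2
#> <motion_model> ester_group: tau0 = 4.33e-11 s, Ea = 6 kJ/mol, C = 1.44e+06 s^-2
#> <motion_model> proton_jump: tau0 = 3.6e-09 s, Ea = 12.9 kJ/mol, C = 2e+07 s^-2
round(fit$rel_uncertainty, 2)
#> whole_molecule.tau0   whole_molecule.ea    ester_group.tau0      ester_group.ea
#>                0.30                0.25                0.35                0.07
#>    proton_jump.tau0      proton_jump.ea
#>                1.16                0.26
```

The weighted residual sum (36.5 for 24 degrees of freedom) says the model
fits the noise; the relative uncertainties say what a single noisy sweep can
and cannot pin down — the activation energy of the dominant ester motion is
determined to a few percent, while the τ₀ intercepts (extrapolations to
1/T = 0) carry tens of percent and the motions can trade roles between
amplitude slots. That asymmetry is intrinsic to BPP fits at this noise
level, not a solver artefact; the vignette quantifies it.

A full per-dose assessment from one seed:

```r
report <- run_assessment(list(seed = 5))
report$table[, c("dose", "delta_e", "conformity", "epr_ratio_to_ref",
                 "content_loss_pct", "dsc_shift")]
#>   dose delta_e conformity epr_ratio_to_ref content_loss_pct dsc_shift
#> 1    0   0.000     1.0000            1.000           0.0000    0.0000
#> 2   25   3.274     0.9999            3.271           0.3928    0.0625
#> 3   50   4.538     0.9998            5.571           0.6686    0.1250
#> 4  100   6.476     0.9992           10.128           1.4699    0.2500
#> 5  200   9.186     0.9970           19.287           0.7499    0.5000
#> 6  400  12.957     0.9905           37.434           2.2605    1.0000
report$verdicts$overall
#> [1]  TRUE  TRUE  TRUE FALSE FALSE FALSE
```

With the default thresholds the standard 25 kGy sterilization dose passes
every check while 400 kGy fails on colour, content loss and melting shift —
the dose–response pattern the battery is designed to resolve.

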