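---
title: "Assessing the radiation stability of solid drugs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the radiation stability of solid drugs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

Electron-beam irradiation at 25 kGy is a pharmacopoeia-accepted way to
sterilize drug substances, but the absorbed dose can also damage them:
radicals are trapped in the crystal lattice, colour centres form, ester bonds
cleave, melting points drift, and assay content falls. `radstab` implements
the measurement models and statistics used to decide whether a solid active
ingredient — the motivating case is the NSAID pair diclofenac (DC) and its
ester prodrug aceclofenac (AC) — tolerates sterilizing doses, and couples
them to seeded synthetic-data generators so every stage of the pipeline can
be validated without instrument files.

## Spin-lattice relaxation over temperature

The core model is dipolar spin-lattice relaxation driven by thermally
activated molecular reorientation. Each motion contributes a BPP spectral
density term, and rates add across motions (the Woessner form for a
multi-proton system):

$$\frac{1}{T_1}(T) \;=\; \sum_i C_i \left[
  \frac{\tau_i}{1 + \omega_0^2 \tau_i^2} +
  \frac{4\tau_i}{1 + 4\omega_0^2 \tau_i^2} \right],
\qquad
\tau_i(T) = \tau_{0,i}\, e^{E_{a,i}/RT},$$

with $\omega_0 = 2\pi\nu$ the proton Larmor angular frequency (25 MHz in the
reference configuration) and $R = 8.314$ J mol$^{-1}$ K$^{-1}$. The
amplitude $C_i = \tfrac{2}{3}\gamma^2 \Delta M_{2,i}$ (units s$^{-2}$)
absorbs the gyromagnetic ratio and the second-moment reduction of motion
$i$; second moments are rarely known independently, so $C_i$ is carried as a
single free constant per motion. A single motion's rate is maximal where
$\omega_0\tau \approx 0.6158$, which is what pins a $T_1$ minimum to a
temperature through the Arrhenius law.

Solid aceclofenac is modelled with three motions: reorientation of the whole
molecule ($\tau_0 = 2.2\times10^{-7}$ s, $E_a = 10.6$ kJ/mol), hindered
rotation of the $-$CH$_2$COOH ester group ($1.9\times10^{-11}$ s, 7.0
kJ/mol), and proton jumps inside hydrogen bonds ($2.8\times10^{-11}$ s, 0.5
kJ/mol). `ac_reference_motions()` carries these values.

### Choice of the default amplitudes

Published activation parameters come without amplitudes, so the package
fixes its defaults once, from the qualitative shape of the measured curve:
a shallow, slightly asymmetric minimum of 58 s in the 140–160 K region,
$T_1$ of order 150 s at 80 K, and a decreasing high-temperature tail as the
whole-molecule motion (whose own minimum lies near the melting range, above
the sweep) gains speed. The defaults are $C = 5\times10^{8}$ s$^{-2}$
(whole molecule), $2\times10^{7}$ s$^{-2}$ (proton jumps), and an
ester-group amplitude calibrated by `calibrate_amplitude()` so that the
model minimum is exactly 58 s ($\approx 1.9\times10^{6}$ s$^{-2}$). At
25 MHz the ester-group Arrhenius crossing $\omega_0\tau = 0.6158$ sits at
158.0 K; the proton-jump term, whose extreme-narrowing rate *decreases* with
temperature, pulls the minimum of the sum slightly below that.

### Fitting

`fit_relaxation_model()` minimizes weighted *rate* residuals,

$$\sum_j \left[\frac{1/T_1^{\mathrm{model}}(T_j) - 1/T_1^{\mathrm{obs}}(T_j)}
  {\sigma_{r,j}}\right]^2,
\qquad \sigma_r = \sigma_{T_1}/T_1^2,$$

because the model is additive in rates and rate weighting keeps the minimum
region and the long-$T_1$ wings on an equal footing. $\tau_0$ and $C$ are
fitted in $\log_{10}$ space (they span decades); $E_a$ linearly in kJ/mol.
Optimization is Levenberg–Marquardt restarted from 32 initializations —
log-uniform $\tau_0 \in [10^{-13}, 10^{-6}]$ s and uniform
$E_a \in [0.1, 30]$ kJ/mol, half of the draws re-anchored so the motion's
BPP crossing falls inside (or just above) the sweep — plus one data-driven
start at the observed rate maximum; ties break on the lower weighted
residual, then on fewer iterations. The incumbent is polished by a short
jittered-restart (basin-hopping) stage. Parameter uncertainties are
reported as relative 1-sigma fractions from the local curvature.

### Identifiability, and why amplitudes can be held fixed

A motion whose correlation time never crosses $1/\omega_0$ inside the sweep
is confined to the slow-motion limit, where the BPP term collapses to
$2C/(\omega_0^2\tau)$: only the ratio $C/\tau_0$ (together with $E_a$) is
then identifiable, and $C$ and $\tau_0$ are exactly degenerate. This is the
situation of the whole-molecule motion at 25 MHz — $\omega_0\tau_0 = 34.6$
already at infinite temperature. `fit_relaxation_model(amplitudes = ...)`
therefore supports holding the amplitudes at known values (from a
second-moment analysis, or from a depth calibration), which restores a
well-posed six-parameter problem; with amplitudes free, reported
whole-molecule $\tau_0$ values should be read as one point on a ridge.
Even with amplitudes fixed, the information geometry is unforgiving: at a
5% relative $T_1$ noise and 30 temperatures in 80–345 K, the Cramér–Rao
bound puts the best attainable relative standard errors for the $\tau_0$
values at several tens of percent (the $\tau_0$ intercept is an
extrapolation of an Arrhenius line to $1/T = 0$, far outside the data), and
a relative bound on an activation energy as small as 0.5 kJ/mol is weaker
still. Fits of this model to single noisy sweeps recover $E_a$ of the
dominant ester motion well, and everything else with wide error bars; the
package reports those error bars rather than hiding them.

The fixed-amplitude pre-fit uses a free-amplitude fit internally (the free
problem is much easier to optimize globally), then maps its motions onto the
amplitude slots along the $C/\tau_0$ ridge as informed starts.

### Saturation recovery

$T_1$ itself comes from magnetization recovery,
$M(t) = M_0(1 - e^{-t/T_1})$, fitted by Levenberg–Marquardt
(`fit_recovery()`) with $T_1$ in log space. A design whose longest delay is
far below the fitted $T_1$ is flagged as ill-conditioned; a non-monotone
binned mean trend marks the fit as non-converged instead of raising. With
20 log-spaced delays up to $5T_1$ and 5% additive noise the estimator sits
on its information bound — a ~7% relative standard error, i.e. a ~5% median
absolute error — which is what the test suite checks against (with sampling
slack), since no estimator can do better at that design.

## EPR processing

Radical content is quantified from first-derivative field sweeps in two
profiles: a low range (15 mT about 338 mT) for narrow lines and an extended
range (500 mT about 336 mT) for broad ones. The chain is:

1. `correct_baseline()` — polynomial (default linear) fitted on the outer
   10% margins of the sweep; margins that visibly contain signal (fit
   residuals above 10% of the sweep amplitude) are halved with a warning.
2. `denoise()` — Savitzky–Golay smoothing (default 25-point window, cubic),
   which preserves line positions and double integrals far better than a
   moving average.
3. `normalize_by_reference()` — every spectrum is scaled so the fitted
   amplitude of an in-cavity reference line (e.g. a TCNQ standard) matches
   the first spectrum's, removing cavity-loading differences, and the fitted
   reference component is subtracted.
4. `double_integrate()` — two cumulative trapezoid passes over a window;
   `per_mass()` divides by sample mass. Only *ratios* of per-mass
   intensities are meaningful without an absolute spin standard.
5. `peak_to_peak_linewidth()` — extremum separation for a single line, or a
   constrained least-squares decomposition into two analytic derivative
   lineshapes when a narrow and a broad component overlap.
6. `g_factor()` — $g = h\nu/\mu_B B$ with CODATA constants, evaluated at
   the derivative zero-crossing between the extrema (robust to asymmetric
   baselines, unlike the sweep centre).

Lineshapes are analytic derivatives of Lorentzian or Gaussian absorption
profiles parameterized by peak-to-peak width and derivative extremum
amplitude, so the double integral scales as amplitude times width squared.
Integration windows should cover the line generously; Lorentzian wings
converge slowly, and a window clipped at a few half-widths biases the
integral (the demo pipeline uses Gaussian shapes for that reason).

## FT-IR conformity

`conformity_factor()` is the Pearson correlation of two spectra resampled
onto the coarser of their grids over 400–4000 cm$^{-1}$ (or any
sub-range). Correlation is invariant to gain and offset, so it isolates
*shape* changes; band-localized damage — e.g. deepening C=O/C–O ester bands
between 1000 and 2000 cm$^{-1}$ — lowers it monotonically with the
perturbation. Both transmittance (as recorded) and absorbance
($A = 2 - \log_{10}\%T$) modes are exposed, since conventions differ;
`band_change_report()` quantifies the mean and maximum transmittance loss
inside a window.

## Colour difference

Powder colour is tracked in CIELAB; the total difference is the CIE76
Euclidean distance $\Delta E = \sqrt{\Delta L^{*2} + \Delta a^{*2} +
\Delta b^{*2}}$ of per-dose mean colours (triplicate means by protocol)
against the unirradiated reference, classified on the conventional verbal
scale (below 1 normally invisible; 1–2 very small; 2–3.5 medium; 3.5–5
obvious, with 5 itself classified as obvious; above 5 very obvious). The
boundary convention — half-open intervals, closed at 5 — is the package's
own, as the verbal scale is customarily quoted without one.

## HPLC validation and content

`fit_calibration()` is ordinary least squares of response on concentration;
`r` is the Pearson coefficient (not $R^2$) and $S_y$ the residual standard
error on $n-2$ degrees of freedom. Detection limits follow the ICH
calibration-line formulas LOD $= 3.3\,S_y/a$ and LOQ $= 10\,S_y/a$.
Repeatability is the sample relative standard deviation of replicate
responses; accuracy is reported as mean recovery of spiked samples read back
through the line — one of several defensible readings of "closeness of
agreement", flagged as such. Content is computed against an external
standard, and `content_loss_table()` subtracts each dose's content from an
*explicitly chosen* reference dose; no unirradiated assay is silently
assumed.

## Thermal analysis

`melting_shift()` is bookkeeping over a dose table of capillary and DSC
melting points. `dsc_peak()` characterizes one endotherm: the peak at the
extremum above a straight line joining the region endpoints (linear baseline
correction), the area as the integral above that line, and the onset by the
standard tangent construction — the steepest leading-edge slope extrapolated
to the baseline.

## The synthetic-data generators

Every generator is seeded explicitly, never touches the global RNG stream,
and returns its noiseless truth alongside the noisy realization so recovery
tests can compare against what was actually simulated.

* **T1 series** — forward model evaluated on 80–345 K (default 5 K steps,
  54 points; the sweep density of a typical overnight run), multiplied by
  lognormal noise with mean-1 factors whose standard deviation equals the
  requested level exactly; relative noise matches how relaxometry
  uncertainties are quoted (±10% in the reference configuration) and keeps
  $T_1$ positive. Per-point uncertainties are set to `noise_level * t1`.
* **Recovery curves** — exponential recovery plus additive Gaussian noise
  scaled to $M_0$.
* **EPR sweeps** — sums of analytic derivative lineshapes, a polynomial
  baseline in a scaled field coordinate, an optional fixed reference line,
  and additive noise scaled to the largest clean amplitude.
* **FT-IR pairs** — 100% transmittance minus Gaussian bands (a schematic
  band set for an aryl-acetic NSAID with an ester linkage is the default);
  the perturbed copy deepens only the bands inside a window, leaving the
  rest bit-identical.
* **HPLC tables** — a straight calibration line with Gaussian response
  noise over six levels spanning 0.50–6.05 $\times 10^{-4}$ g/mL, plus a
  nine-replicate precision table at 2.66 $\times 10^{-4}$ g/mL.
* **Colour series** — L* falling and a*, b* rising with dose as
  $(\mathrm{dose}/400)^{1/2}$, a fast-then-saturating deepening toward
  cream; triplicates with per-channel noise.
* **Thermograms** — a Gaussian endotherm on a linear instrumental baseline,
  with the closed-form area as truth.

What the generators deliberately do **not** emulate: radiolysis chemistry
(dose enters only as a label scaling generator parameters), hyperfine
structure or microwave saturation in EPR, real FT-IR band shapes and
atmospheric artefacts, chromatographic peak shapes, and DSC kinetics.
Passing tests therefore demonstrate that the *processing* recovers what the
measurement models put in at realistic noise — not that those models capture
every feature of real instrument data.

## The assessment pipeline

`run_assessment()` executes all configured modalities over a dose series
from one seed and returns a per-dose table (ΔE and category, conformity
factor, EPR per-mass intensity and ratio to reference, content and content
loss, melting shifts, modelled $T_1$-minimum depth) with verdict flags
against configurable thresholds (defaults: ΔE ≤ 5, conformity ≥ 0.95,
content loss ≤ 2%, |melting shift| ≤ 2 °C). Modalities missing from the
configuration are reported as absent rather than dropped. A YAML
configuration file, a CSV/text report and a manifest (seed, config, package
version) make runs reproducible; with the demo defaults the standard
25 kGy dose passes and 400 kGy fails.

## Numerical choices and limitations

* Degenerate inputs raise early: non-positive temperatures or $T_1$, all
  amplitudes zero (infinite $T_1$), windows outside a sweep, fewer than
  three calibration levels, negative colour differences.
* `find_t1_minimum()` scans a 2000-point grid and refines the bracketed
  interior minimum with golden-section/parabolic search; a boundary minimum
  is flagged rather than reported as interior. `calibrate_amplitude()`
  root-solves the scale of the dominant motion at the minimum to
  $\sim10^{-12}$ relative.
* Problem sizes used in the shipped tests and acceptance script — 30
  temperatures, 20 replicate refits, 100-replicate recovery Monte Carlo,
  2048-point sweeps — are the sizes at which the statistical claims are
  stated; they run in seconds.
* JCAMP-DX support covers plain AFFN tables only, not compressed ASDF
  forms.
* The two-component linewidth decomposition assumes both components share a
  lineshape family and is a local least-squares fit: it needs a sane
  starting width ratio (narrow + broad), which the single-line estimate
  provides.
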