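# Seeded synthetic-data generators for every measurement modality the
# pipeline consumes. Each generator returns the noisy realization together
# with its noiseless ground truth so that recovery tests can compare against
# what was actually simulated. All generators are deterministic for a fixed
# seed and never touch the caller's RNG state.

#' Simulate a T1 temperature series from a relaxation model
#'
#' Evaluates the multi-motion BPP forward model at each temperature and
#' applies multiplicative lognormal noise: measured T1 uncertainties in solid
#' state relaxometry are relative (about +/-10% in the study this package
#' models), and a multiplicative model keeps T1 positive. The lognormal is
#' parameterized so the noise factor has mean 1 and standard deviation
#' exactly `noise_level`.
#'
#' @param motions A [motion_model()] or list thereof (at least one).
#' @param temperatures Temperatures in kelvin, strictly positive. Default
#'   80--345 K in 5 K steps, the span of the temperature sweep emulated.
#' @param larmor_frequency Spectrometer frequency in Hz (default 25 MHz).
#' @param noise_level Fractional noise level (>= 0), default 0.10.
#' @param seed Integer seed.
#' @return A list of class `radstab_sim` with `dataset` (a
#'   [relaxation_dataset()] carrying the noisy T1 and `sigma = noise_level *
#'   t1`), `truth_t1` (noiseless model values), `motions`, `noise_level`,
#'   `seed`.
#' @export
gen_relaxation_dataset <- function(motions, temperatures = seq(80, 345, by = 5),
                                   larmor_frequency = 25e6, noise_level = 0.10,
                                   seed = 1L) {
  motions <- as_motion_list(motions)
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop("`temperatures` must be strictly positive (K)")
  if (noise_level < 0) stop("`noise_level` must be >= 0")
  omega0 <- 2 * pi * larmor_frequency
  truth <- 1 / total_rate(motions, temperatures, omega0)
  if (any(!is.finite(truth)))
    stop("degenerate model: non-finite T1 from the forward model")
  t1 <- if (noise_level > 0) {
    sdlog <- sqrt(log(1 + noise_level^2))
    fac <- local_seed(seed, exp(stats::rnorm(length(truth), -sdlog^2 / 2, sdlog)))
    truth * fac
  } else truth
  structure(list(
    dataset = relaxation_dataset(temperatures, t1, noise_level * t1, larmor_frequency),
    truth_t1 = truth, motions = motions,
    noise_level = noise_level, seed = seed), class = "radstab_sim")
}

#' Simulate a saturation-recovery curve
#'
#' \eqn{M(t) = M_0 (1 - e^{-t/T_1})} plus additive Gaussian noise of standard
#' deviation `noise_level * m0`.
#'
#' @param t1 True relaxation time in seconds (> 0).
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @param delays Recovery delays in seconds (>= 0).
#' @param noise_level Fractional noise level relative to `m0`.
#' @param seed Integer seed.
#' @return List of class `radstab_sim` with `curve` (a [recovery_curve()]),
#'   `truth` (noiseless magnetization), `t1`, `m0`, `seed`.
#' @export
gen_recovery_curve <- function(t1, m0 = 1, delays, noise_level = 0, seed = 1L) {
  if (!is.numeric(t1) || t1 <= 0) stop("`t1` must be positive (s)")
  if (any(delays < 0)) stop("`delays` must be non-negative (s)")
  if (noise_level < 0) stop("`noise_level` must be >= 0")
  truth <- m0 * (1 - exp(-delays / t1))
  mag <- if (noise_level > 0)
    truth + local_seed(seed, stats::rnorm(length(delays), 0, noise_level * m0))
  else truth
  structure(list(curve = recovery_curve(delays, mag, m0_hint = m0),
                 truth = truth, t1 = t1, m0 = m0, seed = seed),
            class = "radstab_sim")
}

# analytic first-derivative lineshapes, parameterized by peak-to-peak width
# and by the derivative extremum amplitude
deriv_line <- function(field, center, width_pp, shape, amplitude) {
  x <- field - center
  if (shape == "gaussian") {
    s <- width_pp / 2
    -amplitude * (x / s) * exp(0.5 * (1 - (x / s)^2))
  } else if (shape == "lorentzian") {
    g <- width_pp * sqrt(3) / 2              # half width at half maximum
    h <- amplitude * 8 * sqrt(3) * g / 9     # absorption peak height
    -2 * h * x / g^2 / (1 + (x / g)^2)^2
  } else stop("shape must be 'gaussian' or 'lorentzian'")
}

#' Simulate a first-derivative EPR field sweep
#'
#' Sum of analytic derivative lineshapes (Lorentzian or Gaussian,
#' parameterized by peak-to-peak width and derivative extremum amplitude), a
#' polynomial baseline, an optional fixed-position reference line (emulating
#' a TCNQ standard in the cavity), and additive Gaussian noise scaled to the
#' largest clean derivative amplitude.
#'
#' @param components List of components, each a list/vector with elements
#'   `center` (mT), `width` (peak-to-peak, mT), `shape` (`"lorentzian"` or
#'   `"gaussian"`), `amplitude` (derivative extremum, a.u.).
#' @param baseline_coeffs Polynomial coefficients (ascending order) in the
#'   scaled coordinate \eqn{u = (B - B_{mid}) / (span/2) \in [-1, 1]}.
#' @param reference Optional reference line, same fields as a component
#'   (default shape `"lorentzian"`). A reference centered outside the sweep
#'   raises a warning, not an error.
#' @param field_grid Strictly increasing field values in mT. Defaults to the
#'   low-range profile: 15 mT sweep about 338 mT.
#' @param noise_level Fractional additive noise relative to the largest clean
#'   signal amplitude.
#' @param microwave_frequency GHz, default 9.457177.
#' @param sample_mass Sample mass in grams (for per-mass intensities).
#' @param seed Integer seed.
#' @return List of class `radstab_sim` with `spectrum` (an [epr_spectrum()]),
#'   and truth components `truth_sample`, `truth_reference`,
#'   `truth_baseline`.
#' @export
gen_epr_spectrum <- function(components = list(),
                             baseline_coeffs = 0,
                             reference = NULL,
                             field_grid = epr_field_grid("low"),
                             noise_level = 0,
                             microwave_frequency = 9.457177,
                             sample_mass = NA_real_,
                             seed = 1L) {
  if (is.unsorted(field_grid, strictly = TRUE))
    stop("`field_grid` must be strictly increasing (mT)")
  if (noise_level < 0) stop("`noise_level` must be >= 0")
  comp_signal <- function(cmp) {
    cmp <- as.list(cmp)
    shape <- if (is.null(cmp$shape)) "lorentzian" else cmp$shape
    if (cmp$width <= 0) stop("component widths must be positive (mT)")
    deriv_line(field_grid, cmp$center, cmp$width, shape, cmp$amplitude)
  }
  sample_sig <- rep(0, length(field_grid))
  for (cmp in components) sample_sig <- sample_sig + comp_signal(cmp)
  ref_sig <- rep(0, length(field_grid))
  if (!is.null(reference)) {
    rc <- as.list(reference)
    if (rc$center < min(field_grid) || rc$center > max(field_grid))
      warning("reference line center lies outside the field sweep")
    ref_sig <- comp_signal(reference)
  }
  mid <- (min(field_grid) + max(field_grid)) / 2
  u <- (field_grid - mid) / (diff(range(field_grid)) / 2)
  base_sig <- rep(0, length(field_grid))
  for (k in seq_along(baseline_coeffs))
    base_sig <- base_sig + baseline_coeffs[k] * u^(k - 1)
  clean <- sample_sig + ref_sig + base_sig
  amp0 <- max(abs(sample_sig + ref_sig))
  sig <- if (noise_level > 0 && amp0 > 0)
    clean + local_seed(seed, stats::rnorm(length(clean), 0, noise_level * amp0))
  else clean
  structure(list(
    spectrum = epr_spectrum(field_grid, sig,
                            microwave_frequency = microwave_frequency,
                            sample_mass = sample_mass),
    truth_sample = sample_sig, truth_reference = ref_sig,
    truth_baseline = base_sig, seed = seed), class = "radstab_sim")
}

#' Default EPR field grids
#'
#' The two sweep profiles used for radical characterization: a low range
#' (15 mT about 338 mT) resolving narrow lines, and an extended range
#' (500 mT about 336 mT) capturing broad components.
#'
#' @param profile `"low"` or `"extended"`.
#' @param n Number of field points.
#' @return Numeric vector of field values in mT.
#' @export
epr_field_grid <- function(profile = c("low", "extended"), n = 2048L) {
  profile <- match.arg(profile)
  if (profile == "low") seq(338 - 7.5, 338 + 7.5, length.out = n)
  else seq(336 - 250, 336 + 250, length.out = n)
}

#' Simulate a matched pair of FT-IR transmittance spectra
#'
#' Builds a reference spectrum as 100% transmittance minus Gaussian
#' absorption bands, then a perturbed copy in which every band inside
#' `perturb_window` is deepened by the factor `1 + perturb_scale` (the
#' band-localized transmittance decrease irradiation produces in the
#' carbonyl/ester region); the spectrum outside the window is bit-identical
#' to the reference. Transmittance is clipped at 0 with a warning.
#'
#' @param base_bands Data frame or list of bands with elements `center`
#'   (cm^-1), `width` (Gaussian sigma, cm^-1), `depth` (% transmittance).
#'   Default [default_ftir_bands()].
#' @param perturb_window Length-2 wavenumber interval (cm^-1), default
#'   `c(1000, 2000)`; must lie inside the grid.
#' @param perturb_scale Fractional band deepening (>= 0).
#' @param grid Wavenumber grid, default 400--4000 cm^-1 at 1 cm^-1.
#' @param noise_level Optional additive transmittance noise (%T units,
#'   fraction of 1%T), default 0.
#' @param seed Integer seed.
#' @return List of class `radstab_sim` with `reference` and `test`
#'   ([spectrum_trace()] objects) plus the noiseless `truth_reference`,
#'   `truth_test`.
#' @export
gen_ftir_pair <- function(base_bands = default_ftir_bands(),
                          perturb_window = c(1000, 2000),
                          perturb_scale = 0,
                          grid = seq(400, 4000, by = 1),
                          noise_level = 0, seed = 1L) {
  bands <- as.data.frame(base_bands)
  stopifnot(all(c("center", "width", "depth") %in% names(bands)))
  if (perturb_window[1] < min(grid) || perturb_window[2] > max(grid))
    stop("`perturb_window` must lie inside the wavenumber grid")
  if (perturb_scale < 0) stop("`perturb_scale` must be >= 0")
  absorb <- function(scale_in_window) {
    a <- rep(0, length(grid))
    inw <- grid >= perturb_window[1] & grid <= perturb_window[2]
    for (i in seq_len(nrow(bands))) {
      band <- bands$depth[i] * exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
      band[inw] <- band[inw] * scale_in_window
      a <- a + band
    }
    a
  }
  ref <- 100 - absorb(1)
  tst <- 100 - absorb(1 + perturb_scale)
  if (any(tst < 0)) {
    warning("perturbation drove transmittance below 0%; clipped")
    tst <- pmax(tst, 0)
  }
  ref <- pmax(ref, 0)
  truth_ref <- ref; truth_tst <- tst
  if (noise_level > 0) {
    eps <- local_seed(seed, matrix(stats::rnorm(2 * length(grid), 0, noise_level), ncol = 2))
    ref <- pmax(ref + eps[, 1], 0); tst <- pmax(tst + eps[, 2], 0)
  }
  structure(list(reference = spectrum_trace(grid, ref),
                 test = spectrum_trace(grid, tst),
                 truth_reference = truth_ref, truth_test = truth_tst,
                 seed = seed), class = "radstab_sim")
}

#' @rdname gen_ftir_pair
#' @export
default_ftir_bands <- function() {
  # schematic band set for an aryl-acetic NSAID with an ester linkage:
  # N-H / O-H stretch, aromatic + aliphatic C-H, ester and acid C=O,
  # aromatic ring modes, C-O stretches, C-Cl out-of-plane region
  data.frame(
    center = c(3320, 3060, 2930, 1770, 1717, 1589, 1450, 1280, 1150, 1055, 766, 745),
    width  = c(60,   25,   25,   12,   14,   10,   12,   15,   14,   12,   8,   8),
    depth  = c(25,   18,   22,   55,   60,   35,   40,   48,   42,   30,   38, 30)
  )
}

#' Simulate HPLC calibration and replicate-precision tables
#'
#' Detector responses follow `slope * concentration + intercept` plus
#' Gaussian noise of standard deviation `sigma_response`; a separate
#' replicate table at a single concentration supports repeatability (RSD)
#' estimation.
#'
#' @param slope,intercept Calibration line parameters (response units per
#'   g/mL, response units).
#' @param sigma_response Gaussian response noise (response units), >= 0.
#' @param concentrations Calibration concentrations in g/mL; at least 3
#'   distinct positive levels. Default: six levels spanning
#'   0.5038e-4 to 6.0456e-4 g/mL.
#' @param replicate_count Number of precision replicates (default 9).
#' @param replicate_concentration Concentration of the precision replicates
#'   (default 2.66e-4 g/mL).
#' @param seed Integer seed.
#' @return List of class `radstab_sim` with `calibration` (data frame
#'   `concentration`, `response`), `replicates` (data frame `replicate`,
#'   `concentration`, `response`) and the noiseless truth (`slope`,
#'   `intercept`, `truth_response`).
#' @export
gen_hplc_tables <- function(slope, intercept = 0, sigma_response = 0,
                            concentrations = seq(0.5038e-4, 6.0456e-4, length.out = 6),
                            replicate_count = 9L,
                            replicate_concentration = 2.66e-4,
                            seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive (g/mL)")
  if (length(unique(concentrations)) < 3L)
    stop("at least 3 distinct concentration levels are required")
  if (sigma_response < 0) stop("`sigma_response` must be >= 0")
  truth <- slope * concentrations + intercept
  truth_rep <- slope * replicate_concentration + intercept
  noise <- local_seed(seed, stats::rnorm(length(truth) + replicate_count, 0, max(sigma_response, 0)))
  if (sigma_response == 0) noise <- rep(0, length(truth) + replicate_count)
  structure(list(
    calibration = data.frame(concentration = concentrations,
                             response = truth + noise[seq_along(truth)]),
    replicates = data.frame(replicate = seq_len(replicate_count),
                            concentration = replicate_concentration,
                            response = truth_rep + noise[length(truth) + seq_len(replicate_count)]),
    slope = slope, intercept = intercept, truth_response = truth,
    seed = seed), class = "radstab_sim")
}

#' Simulate a dose series of CIELAB colours
#'
#' Emulates the radiation-induced drift from white towards cream/yellow: L*
#' decreases while a* and b* increase with absorbed dose, saturating as
#' `(dose/dose_ref)^exponent`. Replicate measurements add Gaussian noise per
#' channel.
#'
#' @param doses Absorbed doses in kGy (must include the reference dose 0 for
#'   downstream difference reports).
#' @param base Reference colour, default `lab_color(93, 0.4, 2.0)` (near-white
#'   powder).
#' @param drift Length-3 total drift `c(dL, da, db)` reached at `dose_ref`.
#' @param dose_ref Dose at which the full drift is reached (kGy).
#' @param exponent Saturation exponent (0.5 gives the fast-then-flattening
#'   deepening observed visually).
#' @param replicates Replicate measurements per dose (default 3).
#' @param noise_sd Per-channel Gaussian noise of a replicate.
#' @param seed Integer seed.
#' @return List of class `radstab_sim` with `records` (a list of
#'   [dose_color_record()]) and `truth` (data frame of noiseless mean Lab per
#'   dose).
#' @export
gen_color_series <- function(doses = c(0, 25, 50, 100, 200, 400),
                             base = lab_color(93, 0.4, 2.0),
                             drift = c(-10, 2, 8), dose_ref = 400,
                             exponent = 0.5, replicates = 3L,
                             noise_sd = 0.05, seed = 1L) {
  stopifnot(length(drift) == 3L, replicates >= 1L, noise_sd >= 0)
  f <- (pmax(doses, 0) / dose_ref)^exponent
  truth <- data.frame(dose = doses,
                      L = base$L + drift[1] * f,
                      a = base$a + drift[2] * f,
                      b = base$b + drift[3] * f)
  eps <- local_seed(seed, array(stats::rnorm(length(doses) * replicates * 3, 0, noise_sd),
                                dim = c(length(doses), replicates, 3)))
  if (noise_sd == 0) eps[] <- 0
  records <- lapply(seq_along(doses), function(i) {
    reps <- lapply(seq_len(replicates), function(r)
      lab_color(truth$L[i] + eps[i, r, 1], truth$a[i] + eps[i, r, 2],
                truth$b[i] + eps[i, r, 3]))
    dose_color_record(doses[i], reps)
  })
  structure(list(records = records, truth = truth, seed = seed),
            class = "radstab_sim")
}

#' Simulate a DSC thermogram with one Gaussian endotherm
#'
#' Heat flow = linear instrumental baseline + Gaussian endotherm of given
#' peak temperature, width and height, plus optional Gaussian noise. The
#' analytic peak area (`height * width * sqrt(2*pi)`) is returned as truth.
#'
#' @param peak_temp Peak temperature in Celsius.
#' @param width Gaussian sigma in Celsius.
#' @param height Peak height (a.u.); positive values are plotted as the
#'   endotherm magnitude.
#' @param baseline Length-2 `c(intercept, slope)` of the linear baseline.
#' @param grid Temperature grid in Celsius (ascending).
#' @param noise_sd Additive noise standard deviation (a.u.).
#' @param seed Integer seed.
#' @return List of class `radstab_sim` with `thermogram` (a [thermogram()])
#'   and `truth_area`.
#' @export
gen_thermogram <- function(peak_temp = 155, width = 2.0, height = 1.0,
                           baseline = c(0.1, 0.002),
                           grid = seq(30, 250, by = 0.25),
                           noise_sd = 0, seed = 1L) {
  stopifnot(width > 0)
  clean <- baseline[1] + baseline[2] * grid +
    height * exp(-(grid - peak_temp)^2 / (2 * width^2))
  hf <- if (noise_sd > 0)
    clean + local_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  else clean
  structure(list(thermogram = thermogram(grid, hf),
                 truth_area = height * width * sqrt(2 * pi), seed = seed),
            class = "radstab_sim")
}
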