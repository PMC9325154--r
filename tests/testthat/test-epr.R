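# EPR processing: baseline, smoothing, reference normalization, double
# integration, linewidths, g-factors.

test_that("baseline correction removes polynomial drift exactly", {
  grid <- epr_field_grid("low", 1024L)
  ramp <- epr_spectrum(grid, 3 + 0.8 * (grid - 338))
  out <- correct_baseline(ramp, order = 1)
  expect_lt(max(abs(out$signal)), 1e-9)

  mean_only <- epr_spectrum(grid, rep(2.5, 1024L))
  expect_lt(max(abs(correct_baseline(mean_only, order = 0)$signal)), 1e-12)
  expect_error(correct_baseline(ramp, order = 4), "between 0 and 3")
})

test_that("a known quadratic baseline under a line is recovered within 1%", {
  sim <- gen_epr_spectrum(
    list(list(center = 338, width = 1.5, shape = "gaussian", amplitude = 5)),
    baseline_coeffs = c(1.5, 0.8, 0.6),
    field_grid = epr_field_grid("low"), noise_level = 0, seed = 1)
  corrected <- correct_baseline(sim$spectrum, order = 2)
  window <- c(333, 343)
  di_truth <- double_integrate(epr_spectrum(sim$spectrum$field, sim$truth_sample),
                               window)
  di_corr <- double_integrate(corrected, window)
  expect_equal(di_corr / di_truth, 1, tolerance = 0.01)
})

test_that("a resolved line inside the margins triggers margin shrinking", {
  grid <- epr_field_grid("low", 1024L)
  edge_line <- deriv_gauss(grid, min(grid) + 0.4, 0.3, 10)
  expect_warning(correct_baseline(epr_spectrum(grid, edge_line + 0.5)),
                 "shrinking")
})

test_that("smoothing is identity at window 1, cuts noise, keeps integrals", {
  grid <- epr_field_grid("low")
  sim <- gen_epr_spectrum(
    list(list(center = 338, width = 1.26, shape = "lorentzian", amplitude = 5)),
    field_grid = grid, noise_level = 0.02, seed = 21)
  s <- sim$spectrum
  expect_identical(denoise(s, window = 1L)$signal, s$signal)
  expect_error(denoise(s, window = 1025L), "too large")
  expect_error(denoise(s, window = 10L), "odd")

  # variance of pure white noise drops at least 5-fold at the default window
  noise <- s$signal - (sim$truth_sample + sim$truth_reference + sim$truth_baseline)
  sm_noise <- denoise(epr_spectrum(grid, noise))$signal
  expect_gt(var(noise) / var(sm_noise), 5)

  # double integral preserved within 0.5%
  sm <- denoise(s)
  w <- c(334, 342)
  expect_equal(double_integrate(sm, w) / double_integrate(s, w), 1,
               tolerance = 0.005)
  expect_true(peak_to_peak_linewidth(sm, w)$found)

  # smoothing bias of the peak-to-peak width (mean over noise draws) < 2%
  widths <- vapply(1:10, function(r) {
    sim_r <- gen_epr_spectrum(
      list(list(center = 338, width = 1.26, shape = "lorentzian", amplitude = 5)),
      field_grid = grid, noise_level = 0.02, seed = 500 + r)
    peak_to_peak_linewidth(denoise(sim_r$spectrum), w)$widths
  }, numeric(1))
  expect_equal(mean(widths), 1.26, tolerance = 0.02)
})

test_that("reference normalization rescales and subtracts the reference line", {
  grid <- epr_field_grid("low")
  mk <- function(sample_amp, ref_amp, seed)
    gen_epr_spectrum(
      list(list(center = 339, width = 1.8, shape = "gaussian", amplitude = sample_amp)),
      reference = list(center = 333, width = 0.15, shape = "gaussian", amplitude = ref_amp),
      field_grid = grid, noise_level = 0, seed = seed)

  a <- mk(5, 3, 1)
  same <- normalize_by_reference(list(a$spectrum, a$spectrum), c(332.3, 333.7),
                                 shape = "gaussian")
  expect_equal(attr(same, "scale_factors"), c(1, 1), tolerance = 1e-9)

  b <- a
  b$spectrum$signal <- 2 * a$spectrum$signal
  halved <- normalize_by_reference(list(a$spectrum, b$spectrum), c(332.3, 333.7),
                                   shape = "gaussian")
  expect_equal(attr(halved, "scale_factors")[2], 0.5, tolerance = 1e-9)
  ref_region <- halved[[2]]$signal[grid > 332.3 & grid < 333.7]
  expect_lt(max(abs(ref_region)), 0.01 * 3)  # residual reference < 1%

  # cavity gain varying +/-30% multiplies sample and reference alike; after
  # normalization the sample double-integral ratio must match the gain-free
  # truth (here 10 / 4)
  s1 <- mk(4 * 1.3, 3 * 1.3, 2); s2 <- mk(10 * 0.7, 3 * 0.7, 3)
  norm <- normalize_by_reference(list(s1$spectrum, s2$spectrum), c(332.3, 333.7),
                                 shape = "gaussian")
  w <- c(335, 343)
  ratio <- double_integrate(norm[[2]], w) / double_integrate(norm[[1]], w)
  expect_equal(ratio / (10 / 4), 1, tolerance = 0.02)

  flat <- epr_spectrum(grid, rep(0, length(grid)))
  expect_error(normalize_by_reference(list(flat), c(332.3, 333.7)),
               "spectrum 1")
})

test_that("double integration is linear and matches the numeric oracle", {
  grid <- epr_field_grid("extended", 4096L)
  w <- c(200, 472)
  zero <- epr_spectrum(grid, rep(0, length(grid)))
  expect_identical(double_integrate(zero, w), 0)

  s1 <- epr_spectrum(grid, deriv_gauss(grid, 336, 15, 2))
  s2 <- epr_spectrum(grid, deriv_gauss(grid, 300, 40, 1))
  lhs <- double_integrate(epr_spectrum(grid, 2.5 * s1$signal + 4 * s2$signal), w)
  rhs <- 2.5 * double_integrate(s1, w) + 4 * double_integrate(s2, w)
  expect_equal(lhs / rhs, 1, tolerance = 1e-9)

  # amplitude doubles intensity; peak-to-peak width doubling quadruples it
  di1 <- double_integrate(s1, w)
  di_amp2 <- double_integrate(epr_spectrum(grid, 2 * s1$signal), w)
  expect_equal(di_amp2 / di1, 2, tolerance = 1e-12)
  di_w2 <- double_integrate(epr_spectrum(grid, deriv_gauss(grid, 336, 30, 2)), w)
  expect_equal(di_w2 / di1, 4, tolerance = 0.01)

  oracle <- oracle_double_integral(function(x) deriv_gauss(x, 336, 15, 2),
                                   w[1], w[2])
  expect_equal(di1 / oracle, 1, tolerance = 1e-4)

  expect_error(double_integrate(s1, c(0, 100)), "outside")
  expect_error(per_mass(di1, 0), "positive")
  expect_equal(per_mass(di1, 0.014), di1 / 0.014)
})

test_that("processing order changes the intensity by less than 1%", {
  sim <- gen_epr_spectrum(
    list(list(center = 338.5, width = 1.75, shape = "gaussian", amplitude = 6)),
    baseline_coeffs = c(0.5, 0.4), field_grid = epr_field_grid("low"),
    noise_level = 0.01, seed = 31)
  w <- c(334.5, 342.5)
  a <- double_integrate(denoise(correct_baseline(sim$spectrum)), w)
  b <- double_integrate(correct_baseline(denoise(sim$spectrum)), w)
  expect_equal(a / b, 1, tolerance = 0.01)
})

test_that("peak-to-peak linewidths are recovered for one and two components", {
  grid <- epr_field_grid("low")
  one <- gen_epr_spectrum(
    list(list(center = 338, width = 1.26, shape = "lorentzian", amplitude = 5)),
    field_grid = grid, noise_level = 0, seed = 1)
  lw <- peak_to_peak_linewidth(one$spectrum, c(334, 342))
  expect_true(lw$found)
  step <- diff(grid)[1]
  expect_lt(abs(lw$widths - 1.26), step * 1.5)

  # overlapping narrow + broad components, widths as in an irradiated ester
  two <- gen_epr_spectrum(
    list(list(center = 338, width = 1.75, shape = "lorentzian", amplitude = 5),
         list(center = 338, width = 4.41, shape = "lorentzian", amplitude = 1.2)),
    field_grid = grid, noise_level = 0, seed = 2)
  lw2 <- peak_to_peak_linewidth(two$spectrum, components = 2)
  expect_true(lw2$found)
  expect_equal(lw2$widths[1], 1.75, tolerance = 0.1)
  expect_equal(lw2$widths[2], 4.41, tolerance = 0.1)

  noise_only <- local({
    set.seed(99)
    epr_spectrum(grid, rnorm(length(grid), 0, 1))
  })
  expect_false(peak_to_peak_linewidth(noise_only)$found)
})

test_that("g-factor follows the resonance relation with CODATA constants", {
  expect_equal(g_factor(338.0, 9.457177), 1.99909431, tolerance = 1e-7)
  expect_equal(field_for_g(2.0023, 9.457177), 337.4588607, tolerance = 1e-7)
  # scale invariance: doubling field and frequency together leaves g unchanged
  expect_equal(g_factor(676.0, 2 * 9.457177), g_factor(338.0, 9.457177))
  expect_error(g_factor(-1, 9.4), "positive")
})

test_that("full quantification reports linewidth, g and per-mass intensity", {
  sim <- gen_epr_spectrum(
    list(list(center = 338.5, width = 1.75, shape = "gaussian", amplitude = 6)),
    baseline_coeffs = c(0.3, 0.5), field_grid = epr_field_grid("low"),
    noise_level = 0.005, sample_mass = 0.007, seed = 41)
  q <- quantify_epr(sim$spectrum, window = c(334.5, 342.5), denoise_window = 25)
  expect_true(q$found)
  expect_equal(q$linewidths, 1.75, tolerance = 0.05)
  expect_equal(q$g_factors, g_factor(338.5, 9.457177), tolerance = 1e-3)
  truth_di <- double_integrate(epr_spectrum(sim$spectrum$field, sim$truth_sample),
                               c(334.5, 342.5))
  expect_equal(q$intensity_per_mass, truth_di / 0.007, tolerance = 0.03)
})

test_that("stable radicals give ratio series near one", {
  expect_equal(radical_stability_ratios(c(100, 99, 101, 100.5)),
               c(1, 0.99, 1.01, 1.005))
  expect_error(radical_stability_ratios(c(0, 1)), "zero")
})
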