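# Generators: determinism, truth retention, noise calibration, degeneracy.

test_that("all generators are byte-identical under a fixed seed", {
  mm <- ac_calibrated()
  a <- gen_relaxation_dataset(mm, noise_level = 0.1, seed = 42)
  b <- gen_relaxation_dataset(mm, noise_level = 0.1, seed = 42)
  expect_identical(a$dataset$t1, b$dataset$t1)
  expect_false(identical(
    a$dataset$t1,
    gen_relaxation_dataset(mm, noise_level = 0.1, seed = 43)$dataset$t1))

  r1 <- gen_recovery_curve(58, 100, delays = seq(0, 300, 10), noise_level = 0.05, seed = 9)
  r2 <- gen_recovery_curve(58, 100, delays = seq(0, 300, 10), noise_level = 0.05, seed = 9)
  expect_identical(r1$curve$magnetization, r2$curve$magnetization)

  cmp <- list(list(center = 338, width = 1.26, shape = "lorentzian", amplitude = 4))
  e1 <- gen_epr_spectrum(cmp, noise_level = 0.01, seed = 5)
  e2 <- gen_epr_spectrum(cmp, noise_level = 0.01, seed = 5)
  expect_identical(e1$spectrum$signal, e2$spectrum$signal)

  h1 <- gen_hplc_tables(4.3e6, 100, 15, seed = 3)
  h2 <- gen_hplc_tables(4.3e6, 100, 15, seed = 3)
  expect_identical(h1$calibration$response, h2$calibration$response)

  c1 <- gen_color_series(seed = 8)
  c2 <- gen_color_series(seed = 8)
  expect_identical(c1$records[[3]]$mean_color$L, c2$records[[3]]$mean_color$L)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_relaxation_dataset(ac_calibrated(), noise_level = 0.1, seed = 1))
  invisible(gen_hplc_tables(4.3e6, 100, 15, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("noiseless T1 series equals the forward model and carries truth", {
  mm <- ac_calibrated()
  temps <- seq(80, 345, by = 5)
  sim <- gen_relaxation_dataset(mm, temps, noise_level = 0, seed = 1)
  expect_equal(sim$dataset$t1, 1 / oracle_rate(mm, temps, OMEGA0_25MHZ),
               tolerance = 1e-12)
  expect_equal(sim$truth_t1, sim$dataset$t1)
  noisy <- gen_relaxation_dataset(mm, temps, noise_level = 0.1, seed = 1)
  expect_equal(noisy$truth_t1, sim$truth_t1)
  expect_equal(noisy$dataset$sigma, 0.1 * noisy$dataset$t1)
})

test_that("multiplicative T1 noise has the configured fractional level", {
  m <- motion_model(1e-11, 5, 1e7)
  temps <- rep(150, 2e4)
  sim <- gen_relaxation_dataset(m, temps, noise_level = 0.1, seed = 77)
  relerr <- (sim$dataset$t1 - sim$truth_t1) / sim$truth_t1
  expect_lt(abs(sd(relerr) / 0.1 - 1), 0.05)
  expect_lt(abs(mean(relerr)), 0.005)
})

test_that("degenerate relaxation models are rejected", {
  zero <- motion_model(1e-11, 5, 0)
  expect_error(gen_relaxation_dataset(zero, noise_level = 0, seed = 1),
               "degenerate")
  expect_error(gen_relaxation_dataset(ac_calibrated(), temperatures = c(-10, 100),
                                      seed = 1),
               "positive")
})

test_that("recovery-curve generator matches its closed form", {
  sim <- gen_recovery_curve(58, 1, delays = c(0, 29, 58, 116, 580), noise_level = 0)
  expect_equal(sim$curve$magnetization[1], 0)
  expect_equal(sim$curve$magnetization[3], 1 - exp(-1), tolerance = 1e-12)
  long <- gen_recovery_curve(58, 1, delays = c(0, 1, 2, 5800), noise_level = 0)
  expect_equal(long$curve$magnetization[4], 1, tolerance = 1e-6)
  expect_error(gen_recovery_curve(-1, 1, delays = 0:5), "positive")
})

test_that("EPR generator honours amplitudes, baseline and reference placement", {
  grid <- epr_field_grid("low")
  zero <- gen_epr_spectrum(list(), baseline_coeffs = 0, field_grid = grid)
  expect_true(all(zero$spectrum$signal == 0))
  expect_warning(
    gen_epr_spectrum(list(), reference = list(center = 500, width = 0.1,
                                              shape = "lorentzian", amplitude = 1),
                     field_grid = grid),
    "outside")
  one <- gen_epr_spectrum(list(list(center = 338, width = 2, shape = "gaussian",
                                    amplitude = 1)), field_grid = grid)
  two <- gen_epr_spectrum(list(list(center = 338, width = 2, shape = "gaussian",
                                    amplitude = 2)), field_grid = grid)
  expect_equal(two$truth_sample, 2 * one$truth_sample, tolerance = 1e-12)
  expect_error(gen_epr_spectrum(list(list(center = 338, width = -1,
                                          shape = "gaussian", amplitude = 1)),
                                field_grid = grid),
               "width")
})

test_that("FT-IR pair perturbation is confined to the requested window", {
  sim <- gen_ftir_pair(perturb_scale = 0.2, seed = 1)
  expect_identical(sim$reference$intensity[sim$reference$wavenumber > 2500],
                   sim$test$intensity[sim$test$wavenumber > 2500])
  inw <- sim$reference$wavenumber >= 1000 & sim$reference$wavenumber <= 2000
  expect_true(any(sim$test$intensity[inw] < sim$reference$intensity[inw]))
  same <- gen_ftir_pair(perturb_scale = 0, seed = 1)
  expect_identical(same$reference$intensity, same$test$intensity)
})

test_that("HPLC generator validates levels and reproduces the exact line", {
  expect_error(gen_hplc_tables(1e6, concentrations = c(1e-4, 2e-4)), "3 distinct")
  sim <- gen_hplc_tables(4.3e6, 100, sigma_response = 0, seed = 1)
  expect_equal(sim$calibration$response,
               4.3e6 * sim$calibration$concentration + 100, tolerance = 1e-12)
})
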