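# Forward model: Arrhenius correlation times, BPP spectral densities,
# additive multi-motion rates, T1 minimum geometry.

test_that("Arrhenius correlation time matches direct evaluation", {
  m <- motion_model(1.9e-11, 7.0, 1e6, "ester_group")
  expect_equal(arrhenius_tau(m, 145), 6.317088375e-9, tolerance = 1e-9)
  flat <- motion_model(3e-11, 0, 1e6)
  expect_equal(arrhenius_tau(flat, 80), 3e-11)
  expect_equal(arrhenius_tau(flat, 300), 3e-11)
  taus <- arrhenius_tau(m, seq(80, 345, 5))
  expect_true(all(diff(taus) < 0))  # strictly decreasing in T for Ea > 0
  expect_error(arrhenius_tau(m, -5), "positive")
})

test_that("BPP rate limits, linearity and maximum location", {
  w0 <- OMEGA0_25MHZ
  expect_equal(bpp_rate(1e6, 0, w0), 0)
  tau <- 10^seq(-12, -6, 0.5)
  expect_equal(bpp_rate(2e6, tau, w0), 2 * bpp_rate(1e6, tau, w0))
  expect_error(bpp_rate(1e6, -1e-9, w0), "non-negative")

  # independently coded golden-section oracle for the maximizing tau
  for (w in c(w0, 2 * pi * 60e6)) {
    f <- function(tt) bpp_rate(1, tt, w)
    tau_hat <- golden_max(f, 0.01 / w, 10 / w)
    expect_lt(abs(w * tau_hat - 0.6158), 1e-3)
    expect_lt(abs(w * bpp_tau_max(w) - 0.6158), 1e-3)
    # bracket value at the maximum
    expect_equal(f(tau_hat) * w, 1.4251757, tolerance = 1e-6)
  }
})

test_that("amplitude converts to a second-moment reduction and back", {
  gamma <- 2.6752218744e8
  m <- motion_model(1.9e-11, 7.0, 1.9e6)
  dm2 <- amplitude_to_dm2(m)
  expect_equal(2 / 3 * gamma^2 * dm2, m$amplitude, tolerance = 1e-12)
  expect_equal(amplitude_to_dm2(0), 0)
})

test_that("total rate is the sum of per-motion contributions", {
  mm <- ac_calibrated()
  temps <- c(80, 145, 300, 345)
  expect_equal(total_rate(mm, temps, OMEGA0_25MHZ),
               oracle_rate(mm, temps, OMEGA0_25MHZ), tolerance = 1e-12)
  single <- mm[[2]]
  expect_equal(total_rate(single, temps, OMEGA0_25MHZ),
               bpp_rate(single$amplitude, arrhenius_tau(single, temps), OMEGA0_25MHZ))
  indiv <- sapply(mm, function(m)
    bpp_rate(m$amplitude, arrhenius_tau(m, 300), OMEGA0_25MHZ))
  expect_equal(total_rate(mm, 300, OMEGA0_25MHZ), sum(indiv), tolerance = 1e-15)
  expect_error(total_rate(list(motion_model(1e-11, 5, 0)), 300, OMEGA0_25MHZ),
               "degenerate")
})

test_that("calibrated reference model has exactly one interior T1 minimum", {
  grid <- seq(80, 345, by = 0.1)
  t1 <- t1_curve(ac_calibrated(), grid, OMEGA0_25MHZ)
  # local minima: derivative sign flips from negative to positive, clustered
  # so that floating-point jitter in flat regions does not double-count
  mins <- grid[which(diff(sign(diff(t1))) == 2)]
  n_min <- if (length(mins)) sum(diff(c(-Inf, mins)) > 1) else 0L
  expect_identical(n_min, 1L)
})

test_that("T1 minimum location, calibration fixed point and frequency scaling", {
  w0 <- OMEGA0_25MHZ
  ester <- motion_model(1.9e-11, 7.0, 1.9e6, "ester_group")
  fm <- find_t1_minimum(ester, w0)
  # oracle: root of the Arrhenius crossing omega0 * tau(T) = 0.6158
  t_oracle <- 7.0e3 / (8.314 * log(bpp_tau_max(w0) / 1.9e-11))
  expect_equal(fm$t_min, t_oracle, tolerance = 1e-6)
  expect_equal(fm$t_min, 157.98, tolerance = 1e-4)
  expect_true(fm$interior)
  # brute-force confirmation on a 0.01 K grid
  g <- seq(80, 345, by = 0.01)
  expect_lt(abs(g[which.min(t1_curve(ester, g, w0))] - fm$t_min), 0.01)

  # amplitude scaling moves the depth, not the position
  half <- motion_model(1.9e-11, 7.0, 0.95e6, "ester_group")
  expect_equal(find_t1_minimum(half, w0)$t_min, fm$t_min, tolerance = 1e-6)
  expect_equal(find_t1_minimum(half, w0)$t1_min, 2 * fm$t1_min, tolerance = 1e-9)

  # calibration fixed point
  cal <- calibrate_amplitude(list(ester), 58, w0)
  expect_equal(find_t1_minimum(cal, w0)$t1_min, 58, tolerance = 1e-9)

  # higher Larmor frequency pushes the minimum to higher temperature
  expect_gt(find_t1_minimum(ester, 2 * w0)$t_min, fm$t_min)

  # monotone model on the range: boundary flag
  slow <- motion_model(2.2e-7, 10.6, 5e8, "whole_molecule")
  expect_false(find_t1_minimum(slow, w0)$interior)
})
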