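# ICH-style validation statistics and dose-wise content accounting.

test_that("calibration fit matches the normal-equations oracle", {
  # hand-checkable toy series
  toy <- fit_calibration(data.frame(concentration = c(1, 2, 3),
                                    response = c(2.1, 3.9, 6.0)))
  expect_equal(toy$slope, 1.95, tolerance = 1e-12)
  expect_equal(toy$intercept, 0.1, tolerance = 1e-10)
  expect_equal(toy$sy, 0.12247449, tolerance = 1e-7)
  expect_equal(toy$r, 0.99901526, tolerance = 1e-7)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    x <- sort(runif(n, 1e-5, 1e-3))
    y <- 5e6 * x + 40 + rnorm(n, 0, 3)
    got <- fit_calibration(data.frame(concentration = x, response = y))
    want <- oracle_ols(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$sy, want$sy, tolerance = 1e-10)
    expect_equal(got$r, want$r, tolerance = 1e-10)
  }
})

test_that("an exact line gives r = 1 and Sy = 0", {
  sim <- gen_hplc_tables(4.3e6, 120, sigma_response = 0, seed = 1)
  fit <- fit_calibration(sim$calibration)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_lt(fit$sy / fit$slope, 1e-12)
  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 1),
                                          response = c(1, 2, 3))),
               "3 distinct|variance")
})

test_that("LOD and LOQ follow 3.3 and 10 times Sy over slope", {
  toy <- fit_calibration(data.frame(concentration = c(1, 2, 3),
                                    response = c(2.1, 3.9, 6.0)))
  lim <- lod_loq(toy)
  expect_equal(lim$lod, 0.20726452, tolerance = 1e-7)
  expect_equal(lim$loq, 0.62807429, tolerance = 1e-7)
  expect_equal(lim$loq / lim$lod, 10 / 3.3, tolerance = 1e-12)
  zero <- toy; zero$slope <- 0
  expect_error(lod_loq(zero), "slope")
})

test_that("RSD is the sample relative standard deviation", {
  expect_equal(precision_rsd(c(99, 100, 101)), 1.0, tolerance = 1e-12)
  expect_equal(precision_rsd(rep(7, 5)), 0)
  x <- c(101.2, 99.7, 100.4, 100.9, 99.1)
  expect_equal(precision_rsd(1000 * x), precision_rsd(x), tolerance = 1e-12)
  expect_error(precision_rsd(c(1, 2)), "3 replicates")
  expect_error(precision_rsd(c(-1, 0, 1)), "zero mean")
})

test_that("replicate precision at the study noise level stays in band", {
  # response noise set for a target RSD near 1.1%
  slope <- 4.3e6; intercept <- 120
  mean_resp <- slope * 2.66e-4 + intercept
  sigma <- 0.011 * mean_resp
  rsds <- vapply(1:100, function(s) {
    sim <- gen_hplc_tables(slope, intercept, sigma, seed = 6000 + s)
    precision_rsd(sim$replicates$response)
  }, numeric(1))
  expect_gte(mean(rsds >= 0.5 & rsds <= 2.0), 0.95)
})

test_that("content versus standard is proportional to response", {
  expect_equal(content_vs_standard(1250, 1250), 100)
  expect_equal(content_vs_standard(625, 1250), 50)
  expect_equal(content_vs_standard(1250, 1250, standard_assigned = 99.5), 99.5)
  expect_error(content_vs_standard(1, 0), "positive")
})

test_that("content loss table reproduces the printed dose differences", {
  # assay contents of the diclofenac dose series
  dc <- data.frame(dose = c(25, 50, 100, 200, 400),
                   content = c(98.64, 98.65, 98.67, 98.57, 96.86))
  loss <- content_loss_table(dc, reference_dose = 25)
  expect_equal(loss$loss_pct[loss$dose == 400], 1.78, tolerance = 1e-12)
  expect_equal(loss$loss_pct[loss$dose == 25], 0)
  # losses are anti-monotone in content
  expect_equal(order(loss$loss_pct), order(-loss$content))
  expect_error(content_loss_table(dc, reference_dose = 0), "not present")
})

test_that("accuracy is reported as mean recovery of spiked samples", {
  fit <- fit_calibration(data.frame(concentration = c(1e-4, 2e-4, 3e-4, 4e-4),
                                    response = c(430, 860, 1290, 1720)))
  acc <- accuracy_recovery(fit, responses = c(1290, 1296, 1284),
                           expected_concentration = 3e-4)
  expect_equal(acc$mean_recovery_pct, 100, tolerance = 0.01)
  expect_length(acc$recoveries_pct, 3)
})

test_that("the validation report assembles every ICH field", {
  sim <- gen_hplc_tables(4.3e6, 120, sigma_response = 10, seed = 12)
  rep <- validation_report(sim$calibration, sim$replicates$response,
                           accuracy_responses = sim$replicates$response,
                           accuracy_concentration = 2.66e-4)
  expect_named(rep, c("fit", "linearity_range", "r", "rsd_pct", "lod", "loq",
                      "accuracy"))
  expect_equal(rep$linearity_range, range(sim$calibration$concentration))
  expect_gt(rep$r, 0.999)
  expect_lt(rep$lod, min(sim$calibration$concentration))
})
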