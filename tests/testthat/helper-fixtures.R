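# Shared fixtures, built in code at test time.

OMEGA0_25MHZ <- 2 * pi * 25e6

# Table-style reference motions for non-irradiated aceclofenac with the
# package's default amplitudes, ester amplitude calibrated to a 58 s minimum
ac_calibrated <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- calibrate_amplitude(ac_reference_motions(), 58, OMEGA0_25MHZ)
    memo
  }
})

# independent brute-force rate summation (oracle for total_rate)
oracle_rate <- function(motions, temperature, omega0) {
  out <- rep(0, length(temperature))
  for (m in motions) {
    tau <- m$tau0 * exp(m$ea * 1000 / (8.314 * temperature))
    out <- out + m$amplitude * (tau / (1 + omega0^2 * tau^2) +
                                4 * tau / (1 + 4 * omega0^2 * tau^2))
  }
  out
}

# independent golden-section maximizer (oracle for the BPP maximum)
golden_max <- function(f, lo, hi, tol = 1e-12) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  while (abs(b - a) > tol * (abs(a) + abs(b))) {
    if (f(c) > f(d)) b <- d else a <- c
    c <- b - phi * (b - a); d <- a + phi * (b - a)
  }
  (a + b) / 2
}

# closed-form normal-equations OLS (oracle for fit_calibration)
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       sy = sqrt(sum(res^2) / (length(x) - 2)),
       r = sxy / sqrt(sxx * sum((y - mean(y))^2)))
}

# high-resolution trapezoid double integral of an analytic derivative line
# (oracle for double_integrate on fixtures)
oracle_double_integral <- function(fun, lo, hi, n = 200001L) {
  x <- seq(lo, hi, length.out = n)
  y <- fun(x)
  absorb <- cumsum(c(0, (y[-1] + y[-n]) / 2 * diff(x)))
  sum((absorb[-1] + absorb[-n]) / 2 * diff(x))
}

# derivative-Gaussian lineshape used to build EPR fixtures in tests
deriv_gauss <- function(field, center, width_pp, amplitude) {
  s <- width_pp / 2
  x <- field - center
  -amplitude * (x / s) * exp(0.5 * (1 - (x / s)^2))
}
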