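#' Temperature series of spin-lattice relaxation times
#'
#' Container for a measured (or simulated) \eqn{T_1(T)} series together with
#' per-point uncertainties and the Larmor frequency of the spectrometer.
#'
#' @param temperatures Temperatures in kelvin, strictly positive; stored
#'   sorted ascending.
#' @param t1 Relaxation times in seconds, strictly positive.
#' @param sigma Absolute 1-sigma uncertainties of `t1` in seconds (same
#'   length); may be zero for noiseless synthetic data.
#' @param larmor_frequency Spectrometer frequency in Hz (25 MHz in the solid
#'   state study this package models); the angular frequency
#'   \eqn{\omega_0 = 2\pi\nu} is stored alongside.
#'
#' @return An object of class `relaxation_dataset`: a list with elements
#'   `temperatures`, `t1`, `sigma`, `larmor_frequency`, `omega0`.
#' @export
relaxation_dataset <- function(temperatures, t1, sigma = rep(0, length(t1)),
                               larmor_frequency = 25e6) {
  stopifnot(is.numeric(temperatures), is.numeric(t1), is.numeric(sigma))
  n <- length(temperatures)
  if (length(t1) != n || length(sigma) != n)
    stop("`temperatures`, `t1` and `sigma` must have equal length")
  if (n == 0L) stop("empty dataset")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop("temperatures must be strictly positive (K)")
  if (any(!is.finite(t1)) || any(t1 <= 0)) stop("t1 values must be strictly positive (s)")
  if (any(sigma < 0)) stop("uncertainties must be non-negative")
  if (length(larmor_frequency) != 1L || larmor_frequency <= 0)
    stop("`larmor_frequency` must be a single positive frequency (Hz)")
  o <- order(temperatures)
  structure(list(temperatures = temperatures[o], t1 = t1[o], sigma = sigma[o],
                 larmor_frequency = larmor_frequency,
                 omega0 = 2 * pi * larmor_frequency),
            class = "relaxation_dataset")
}

#' @export
print.relaxation_dataset <- function(x, ...) {
  cat(sprintf("<relaxation_dataset> %d points, %.0f-%.0f K, %.3g MHz, T1 %.3g-%.3g s\n",
              length(x$t1), min(x$temperatures), max(x$temperatures),
              x$larmor_frequency / 1e6, min(x$t1), max(x$t1)))
  invisible(x)
}

#' @export
as.data.frame.relaxation_dataset <- function(x, ...) {
  data.frame(temperature_K = x$temperatures, t1_s = x$t1, sigma_s = x$sigma)
}

#' Read / write a delimited T1 table
#'
#' Comma-separated, header row, dot decimal; columns `temperature_K`, `t1_s`
#' and optionally `sigma_s`.
#'
#' @param path File path.
#' @param larmor_frequency Spectrometer frequency in Hz attached on read.
#' @return `read_t1_table()` returns a [relaxation_dataset()].
#' @export
read_t1_table <- function(path, larmor_frequency = 25e6) {
  d <- utils::read.csv(path)
  need <- c("temperature_K", "t1_s")
  if (!all(need %in% names(d)))
    stop("T1 table must have columns temperature_K, t1_s (optional sigma_s)")
  sigma <- if ("sigma_s" %in% names(d)) d$sigma_s else rep(0, nrow(d))
  relaxation_dataset(d$temperature_K, d$t1_s, sigma, larmor_frequency)
}

#' @rdname read_t1_table
#' @param dataset A [relaxation_dataset()].
#' @export
write_t1_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Saturation-recovery magnetization curve
#'
#' Delay series and recovered magnetization following the single-exponential
#' law \eqn{M(t) = M_0 (1 - e^{-t/T_1})}.
#'
#' @param delays Recovery delays in seconds, non-negative; at least 4 points
#'   are required for fitting.
#' @param magnetization Magnetization values (arbitrary units).
#' @param m0_hint Optional equilibrium-magnetization hint used to seed fits.
#' @return An object of class `recovery_curve`.
#' @export
recovery_curve <- function(delays, magnetization, m0_hint = NULL) {
  stopifnot(is.numeric(delays), is.numeric(magnetization))
  if (length(delays) != length(magnetization))
    stop("`delays` and `magnetization` must have equal length")
  if (any(delays < 0)) stop("delays must be non-negative (s)")
  if (length(unique(delays)) < 4L)
    stop("at least 4 distinct delays are required")
  o <- order(delays)
  structure(list(delays = delays[o], magnetization = magnetization[o],
                 m0_hint = m0_hint),
            class = "recovery_curve")
}
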