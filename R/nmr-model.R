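#' Thermally activated molecular motion
#'
#' Describes one reorientational motion contributing to dipolar spin-lattice
#' relaxation: an Arrhenius-activated correlation time and a relaxation
#' amplitude. The amplitude is the combined constant
#' \eqn{C = (2/3)\,\gamma^2\,\Delta M_2} (units \eqn{s^{-2}}), i.e. the
#' proton gyromagnetic ratio and the second-moment reduction of the motion are
#' absorbed into a single free parameter.
#'
#' @param tau0 Pre-exponential correlation time \eqn{\tau_0} in seconds
#'   (must be > 0).
#' @param ea Activation energy \eqn{E_a} in kJ/mol (must be >= 0).
#' @param amplitude Relaxation amplitude \eqn{C} in \eqn{s^{-2}} (must be >= 0).
#' @param label Free-text label, conventionally one of `"whole_molecule"`,
#'   `"ester_group"`, `"proton_jump"`.
#'
#' @return An object of class `motion_model`.
#' @seealso [arrhenius_tau()], [bpp_rate()], [total_rate()]
#' @export
#' @examples
#' m <- motion_model(tau0 = 1.9e-11, ea = 7.0, amplitude = 1.9e6,
#'                   label = "ester_group")
#' arrhenius_tau(m, 145)
motion_model <- function(tau0, ea, amplitude, label = "motion") {
  stopifnot(is.numeric(tau0), length(tau0) == 1L,
            is.numeric(ea), length(ea) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L)
  if (!is.finite(tau0) || tau0 <= 0) stop("`tau0` must be a positive finite number (s)")
  if (!is.finite(ea) || ea < 0) stop("`ea` must be a non-negative finite number (kJ/mol)")
  if (!is.finite(amplitude) || amplitude < 0) stop("`amplitude` must be non-negative (s^-2)")
  structure(list(label = as.character(label), tau0 = tau0, ea = ea,
                 amplitude = amplitude),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> %s: tau0 = %.3g s, Ea = %.3g kJ/mol, C = %.3g s^-2\n",
              x$label, x$tau0, x$ea, x$amplitude))
  invisible(x)
}

as_motion_list <- function(motions) {
  if (inherits(motions, "motion_model")) motions <- list(motions)
  if (!is.list(motions) || length(motions) == 0L ||
      !all(vapply(motions, inherits, logical(1), "motion_model")))
    stop("`motions` must be a motion_model or a non-empty list of motion_model objects")
  motions
}

#' Reference three-motion parameter set for solid aceclofenac
#'
#' The three reorientations resolved in non-irradiated solid aceclofenac at
#' 25 MHz: whole-molecule reorientation (tau0 = 2.2e-7 s, Ea = 10.6 kJ/mol),
#' hindered rotation of the -CH2COOH ester group (1.9e-11 s, 7.0 kJ/mol) and
#' proton jumps in hydrogen bonds (2.8e-11 s, 0.5 kJ/mol). Relaxation
#' amplitudes are not published; the defaults here reproduce a shallow,
#' slightly asymmetric T1 minimum in the 140--160 K region with a decreasing
#' high-temperature tail, and are intended to be rescaled with
#' [calibrate_amplitude()] against an observed minimum depth.
#'
#' @param amplitudes Numeric length-3 vector of amplitudes (s^-2) for the
#'   whole-molecule, ester-group and proton-jump motions, in that order.
#' @return A list of three [motion_model()] objects.
#' @export
#' @examples
#' curve <- t1_curve(ac_reference_motions(), seq(80, 345, 5), omega0 = 2 * pi * 25e6)
ac_reference_motions <- function(amplitudes = c(5e8, 1.9e6, 2e7)) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) == 3L)
  list(
    motion_model(2.2e-7,  10.6, amplitudes[1], "whole_molecule"),
    motion_model(1.9e-11,  7.0, amplitudes[2], "ester_group"),
    motion_model(2.8e-11,  0.5, amplitudes[3], "proton_jump")
  )
}

#' Convert a relaxation amplitude to a second-moment reduction
#'
#' The fitted amplitude is \eqn{C = (2/3)\gamma^2 \Delta M_2}; given the
#' proton gyromagnetic ratio this inverts to the second-moment reduction
#' \eqn{\Delta M_2 = 3C / (2\gamma^2)} in field-squared units (T^2).
#'
#' @param amplitude Relaxation amplitude in \eqn{s^{-2}} (or a
#'   [motion_model()]).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (default: protons).
#' @return Second-moment reduction in T^2.
#' @export
amplitude_to_dm2 <- function(amplitude, gamma = GAMMA_PROTON) {
  if (inherits(amplitude, "motion_model")) amplitude <- amplitude$amplitude
  stopifnot(is.numeric(amplitude), all(amplitude >= 0), gamma > 0)
  3 * amplitude / (2 * gamma^2)
}

#' Arrhenius correlation time
#'
#' \eqn{\tau_c(T) = \tau_0 \exp(E_a / RT)} with \eqn{R} = 8.314 J/mol/K and
#' `ea` converted from kJ/mol to J/mol internally.
#'
#' @param motion A [motion_model()].
#' @param temperature Temperature(s) in kelvin; must be strictly positive.
#' @return Correlation time(s) in seconds.
#' @export
arrhenius_tau <- function(motion, temperature) {
  stopifnot(inherits(motion, "motion_model"), is.numeric(temperature))
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("`temperature` must be strictly positive (K)")
  motion$tau0 * exp(motion$ea * 1000 / (R_GAS * temperature))
}

#' BPP spectral-density rate contribution
#'
#' Single-motion dipolar relaxation rate
#' \deqn{(1/T_1)^* = C \left[ \frac{\tau}{1+\omega_0^2\tau^2} +
#'   \frac{4\tau}{1+4\omega_0^2\tau^2} \right],}
#' the standard BPP form with the \eqn{2/3\,\gamma^2\,\Delta M_2} prefactor
#' absorbed into `amplitude`. The rate over \eqn{\tau} is maximal at
#' \eqn{\omega_0\tau \approx 0.6158}, which locates the T1 minimum of a
#' thermally activated motion.
#'
#' @param amplitude Amplitude \eqn{C} in \eqn{s^{-2}}.
#' @param tau Correlation time(s) in seconds (>= 0).
#' @param omega0 Larmor angular frequency in rad/s (> 0).
#' @return Rate contribution(s) in \eqn{s^{-1}}.
#' @export
bpp_rate <- function(amplitude, tau, omega0) {
  stopifnot(is.numeric(amplitude), is.numeric(tau), is.numeric(omega0))
  if (any(tau < 0)) stop("`tau` must be non-negative (s)")
  if (any(omega0 <= 0)) stop("`omega0` must be positive (rad/s)")
  amplitude * (tau / (1 + (omega0 * tau)^2) + 4 * tau / (1 + (2 * omega0 * tau)^2))
}

#' Total multi-motion relaxation rate
#'
#' Sum of [bpp_rate()] contributions over a list of motions, each with its
#' Arrhenius correlation time evaluated at `temperature` (the Woessner
#' additive-rate form for a multi-proton system).
#'
#' @param motions A [motion_model()] or list thereof (non-empty).
#' @param temperature Temperature(s) in kelvin.
#' @param omega0 Larmor angular frequency in rad/s.
#' @return Total rate \eqn{1/T_1} in \eqn{s^{-1}} (same length as
#'   `temperature`).
#' @export
total_rate <- function(motions, temperature, omega0) {
  motions <- as_motion_list(motions)
  if (all(vapply(motions, function(m) m$amplitude, numeric(1)) == 0))
    stop("degenerate model: all motion amplitudes are zero (infinite T1)")
  rate <- 0
  for (m in motions)
    rate <- rate + bpp_rate(m$amplitude, arrhenius_tau(m, temperature), omega0)
  rate
}

#' Model T1 curve over temperature
#'
#' Convenience wrapper returning \eqn{T_1(T) = 1/\sum_i (1/T_1)_i}.
#'
#' @inheritParams total_rate
#' @return Numeric vector of T1 values in seconds.
#' @export
t1_curve <- function(motions, temperature, omega0) {
  1 / total_rate(motions, temperature, omega0)
}
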