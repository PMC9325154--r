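#' FT-IR spectrum trace
#'
#' @param wavenumber Wavenumbers in cm^-1; stored sorted ascending.
#' @param intensity Transmittance in % (0--102, small tolerance for
#'   instrument overshoot) or absorbance when `mode = "absorbance"`.
#' @param mode `"transmittance"` (default) or `"absorbance"`.
#' @return Object of class `spectrum_trace`.
#' @export
spectrum_trace <- function(wavenumber, intensity, mode = c("transmittance", "absorbance")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(wavenumber), is.numeric(intensity))
  if (length(wavenumber) != length(intensity))
    stop("`wavenumber` and `intensity` lengths differ")
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]; intensity <- intensity[o]
  if (any(duplicated(wavenumber))) stop("duplicated wavenumbers")
  if (mode == "transmittance" && (any(intensity < 0) || any(intensity > 102)))
    stop("transmittance must lie within [0, 102] %")
  structure(list(wavenumber = wavenumber, intensity = intensity, mode = mode),
            class = "spectrum_trace")
}

#' @export
print.spectrum_trace <- function(x, ...) {
  cat(sprintf("<spectrum_trace> %d points, %.0f-%.0f cm^-1 (%s)\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber), x$mode))
  invisible(x)
}

#' Convert a transmittance trace to absorbance
#'
#' \eqn{A = 2 - \log_{10}(\%T)}; zero transmittance is floored at a small
#' positive value to keep the absorbance finite.
#'
#' @param trace A [spectrum_trace()] in transmittance mode.
#' @return A [spectrum_trace()] in absorbance mode.
#' @export
to_absorbance <- function(trace) {
  stopifnot(inherits(trace, "spectrum_trace"))
  if (trace$mode == "absorbance") return(trace)
  spectrum_trace(trace$wavenumber, 2 - log10(pmax(trace$intensity, 1e-6)),
                 mode = "absorbance")
}

# resample both traces onto the coarser of the two grids restricted to range
.common_grid <- function(reference, test, range) {
  lo <- max(min(reference$wavenumber), min(test$wavenumber), range[1])
  hi <- min(max(reference$wavenumber), max(test$wavenumber), range[2])
  if (!(hi > lo)) stop("no common wavenumber support in the requested range")
  step <- max(stats::median(diff(reference$wavenumber)),
              stats::median(diff(test$wavenumber)))
  grid <- seq(lo, hi, by = step)
  list(grid = grid,
       ref = stats::approx(reference$wavenumber, reference$intensity, grid)$y,
       tst = stats::approx(test$wavenumber, test$intensity, grid)$y)
}

#' Spectral conformity (purity) factor
#'
#' Pearson correlation of the two spectra's intensities over a common
#' wavenumber grid (both traces are linearly resampled to the coarser of the
#' two grids). Identical or affinely related spectra give 1; band-localized
#' changes lower the factor towards the values typical of radiation-damaged
#' material.
#'
#' @param reference,test [spectrum_trace()] objects in the same mode.
#' @param range Wavenumber interval, default `c(400, 4000)`.
#' @param mode Compare `"transmittance"` (as recorded) or `"absorbance"`
#'   (traces converted first).
#' @return Correlation in \[-1, 1\].
#' @export
conformity_factor <- function(reference, test, range = c(400, 4000),
                              mode = c("transmittance", "absorbance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "spectrum_trace"), inherits(test, "spectrum_trace"))
  if (mode == "absorbance") { reference <- to_absorbance(reference); test <- to_absorbance(test) }
  g <- .common_grid(reference, test, range)
  if (stats::sd(g$ref) == 0 || stats::sd(g$tst) == 0)
    stop("undefined correlation: a spectrum is constant over the range")
  stats::cor(g$ref, g$tst)
}

#' Band-localized transmittance change
#'
#' Mean and maximum decrease of the test spectrum relative to the reference
#' inside `window`, with a flag when the mean decrease exceeds `threshold`.
#'
#' @param reference,test [spectrum_trace()] objects (transmittance mode).
#' @param window Wavenumber interval, default the ester/carbonyl region
#'   `c(1000, 2000)`.
#' @param threshold Mean-decrease flag threshold in %T (default 1).
#' @return List with `mean_decrease`, `max_decrease` (both %T, positive =
#'   transmittance loss) and logical `flagged`.
#' @export
band_change_report <- function(reference, test, window = c(1000, 2000),
                               threshold = 1) {
  stopifnot(inherits(reference, "spectrum_trace"), inherits(test, "spectrum_trace"))
  g <- .common_grid(reference, test, window)
  d <- g$ref - g$tst
  list(mean_decrease = mean(d), max_decrease = max(d),
       flagged = mean(d) > threshold)
}

#' Read / write a delimited FT-IR trace
#'
#' Two-column CSV (`wavenumber_cm1`, `transmittance_pct`) with a header row.
#'
#' @param path File path.
#' @return `read_ftir_table()` returns a [spectrum_trace()].
#' @export
read_ftir_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("wavenumber_cm1", "transmittance_pct") %in% names(d)))
    stop("FT-IR table must have columns wavenumber_cm1, transmittance_pct")
  spectrum_trace(d$wavenumber_cm1, d$transmittance_pct)
}

#' @rdname read_ftir_table
#' @param trace A [spectrum_trace()].
#' @export
write_ftir_table <- function(trace, path) {
  stopifnot(inherits(trace, "spectrum_trace"))
  utils::write.csv(data.frame(wavenumber_cm1 = trace$wavenumber,
                              transmittance_pct = trace$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
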