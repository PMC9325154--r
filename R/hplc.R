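#' HPLC calibration series
#'
#' @param concentrations Analyte concentrations in g/mL; at least 3 distinct
#'   positive levels.
#' @param responses Integrated detector responses (a.u.), same length.
#' @return Object of class `calibration_series`.
#' @export
calibration_series <- function(concentrations, responses) {
  stopifnot(is.numeric(concentrations), is.numeric(responses))
  if (length(concentrations) != length(responses))
    stop("`concentrations` and `responses` lengths differ")
  if (any(concentrations <= 0)) stop("concentrations must be positive (g/mL)")
  if (length(unique(concentrations)) < 3L)
    stop("at least 3 distinct concentration levels are required")
  structure(list(concentrations = concentrations, responses = responses),
            class = "calibration_series")
}

#' Ordinary least-squares calibration fit
#'
#' Linear regression of response on concentration with the Pearson
#' correlation coefficient `r` (of concentration and response, not R
#' squared) and the residual standard error `Sy` on n - 2 degrees of
#' freedom.
#'
#' @param series A [calibration_series()] or a data frame with columns
#'   `concentration` and `response`.
#' @return Object of class `calibration_fit`: `slope`, `intercept`, `r`,
#'   `sy`, `n`.
#' @export
fit_calibration <- function(series) {
  if (is.data.frame(series))
    series <- calibration_series(series$concentration, series$response)
  stopifnot(inherits(series, "calibration_series"))
  x <- series$concentrations; y <- series$responses
  if (stats::var(x) == 0) stop("zero concentration variance")
  fit <- stats::lm(y ~ x)
  n <- length(x)
  sy <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, y), sy = sy, n = n),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> n = %d, slope = %.6g, intercept = %.6g, r = %.4f, Sy = %.4g\n",
              x$n, x$slope, x$intercept, x$r, x$sy))
  invisible(x)
}

#' Limits of detection and quantification
#'
#' ICH signal-to-noise free formulas from the calibration line:
#' LOD = 3.3 Sy / a, LOQ = 10 Sy / a, where `Sy` is the residual standard
#' error and `a` the slope.
#'
#' @param fit A [fit_calibration()] result.
#' @return List with `lod` and `loq` in g/mL.
#' @export
lod_loq <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("zero slope: LOD/LOQ undefined")
  list(lod = 3.3 * fit$sy / abs(fit$slope),
       loq = 10 * fit$sy / abs(fit$slope))
}

#' Relative standard deviation of replicate responses
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#'
#' @param replicates At least 3 replicate responses with non-zero mean.
#' @return RSD in percent.
#' @export
precision_rsd <- function(replicates) {
  stopifnot(is.numeric(replicates))
  if (length(replicates) < 3L) stop("at least 3 replicates are required")
  m <- mean(replicates)
  if (m == 0) stop("zero mean response: RSD undefined")
  100 * stats::sd(replicates) / m
}

#' Mean recovery accuracy
#'
#' Closeness of agreement between determined and expected concentrations,
#' reported as the mean recovery percentage of spiked samples with known
#' concentration read back through the calibration line.
#'
#' @param fit A [fit_calibration()] result.
#' @param responses Observed responses of the spiked samples.
#' @param expected_concentration Known spiked concentration (g/mL).
#' @return List with `mean_recovery_pct` and the individual `recoveries_pct`.
#' @export
accuracy_recovery <- function(fit, responses, expected_concentration) {
  stopifnot(inherits(fit, "calibration_fit"), expected_concentration > 0)
  found <- (responses - fit$intercept) / fit$slope
  rec <- 100 * found / expected_concentration
  list(mean_recovery_pct = mean(rec), recoveries_pct = rec)
}

#' Content relative to an external standard
#'
#' `content = standard_assigned * sample_response / standard_response`.
#'
#' @param sample_response Integrated response of the sample.
#' @param standard_response Integrated response of the standard (> 0).
#' @param standard_assigned Assigned content of the standard in % (default
#'   100).
#' @return Content in %.
#' @export
content_vs_standard <- function(sample_response, standard_response,
                                standard_assigned = 100) {
  if (any(standard_response <= 0)) stop("standard response must be positive")
  standard_assigned * sample_response / standard_response
}

#' Content record at one absorbed dose
#'
#' @param dose Absorbed dose in kGy.
#' @param content Determined content in % of standard (>= 0).
#' @return Object of class `content_record`.
#' @export
content_record <- function(dose, content) {
  stopifnot(is.numeric(dose), is.numeric(content), length(dose) == length(content))
  if (any(content < 0)) stop("content must be non-negative (%)")
  structure(list(dose = dose, content = content), class = "content_record")
}

#' Per-dose content loss against a reference dose
#'
#' `loss = content(reference) - content(dose)` for every dose in the records.
#' The reference dose must be given explicitly (an unirradiated assay is not
#' assumed to be present).
#'
#' @param records A [content_record()] (vectorized) or data frame with
#'   columns `dose` and `content`.
#' @param reference_dose Dose whose content anchors the losses.
#' @return Data frame with `dose`, `content`, `loss_pct`.
#' @export
content_loss_table <- function(records, reference_dose) {
  if (inherits(records, "content_record"))
    records <- data.frame(dose = records$dose, content = records$content)
  stopifnot(is.data.frame(records), all(c("dose", "content") %in% names(records)))
  iref <- which(records$dose == reference_dose)
  if (!length(iref)) stop("reference dose ", reference_dose, " kGy not present")
  ref <- records$content[iref[1]]
  o <- order(records$dose)
  data.frame(dose = records$dose[o], content = records$content[o],
             loss_pct = ref - records$content[o])
}

#' ICH-style validation report
#'
#' Assembles linearity, precision, accuracy and detection-limit statistics
#' into one list mirroring a method-validation summary.
#'
#' @param calibration A data frame (`concentration`, `response`) or
#'   [calibration_series()].
#' @param replicates Replicate responses at one concentration.
#' @param accuracy_responses Optional responses of spiked samples.
#' @param accuracy_concentration Known concentration of the spiked samples.
#' @return List with `fit`, `linearity_range`, `r`, `rsd_pct`, `lod`, `loq`
#'   and optionally `accuracy`.
#' @export
validation_report <- function(calibration, replicates,
                              accuracy_responses = NULL,
                              accuracy_concentration = NULL) {
  fit <- fit_calibration(calibration)
  conc <- if (is.data.frame(calibration)) calibration$concentration
          else calibration$concentrations
  lims <- lod_loq(fit)
  out <- list(fit = fit,
              linearity_range = range(conc),
              r = fit$r,
              rsd_pct = precision_rsd(replicates),
              lod = lims$lod, loq = lims$loq)
  if (!is.null(accuracy_responses) && !is.null(accuracy_concentration))
    out$accuracy <- accuracy_recovery(fit, accuracy_responses, accuracy_concentration)
  out
}
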