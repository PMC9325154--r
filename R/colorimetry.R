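#' CIELAB colour triplet
#'
#' @param L Luminosity L* in \[0, 100\].
#' @param a Red-green axis a* (positive = reddish).
#' @param b Yellow-blue axis b* (positive = yellowish).
#' @return Object of class `lab_color`.
#' @export
lab_color <- function(L, a, b) {
  stopifnot(is.numeric(L), is.numeric(a), is.numeric(b),
            length(L) == 1L, length(a) == 1L, length(b) == 1L)
  if (!is.finite(L) || L < 0 || L > 100) stop("L* must lie in [0, 100]")
  structure(list(L = L, a = a, b = b), class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("<lab_color> L* = %.2f, a* = %.2f, b* = %.2f\n", x$L, x$a, x$b))
  invisible(x)
}

#' Replicated colour measurement at one absorbed dose
#'
#' @param dose Absorbed dose in kGy.
#' @param replicates Non-empty list of [lab_color()] (three replicates in the
#'   measurement protocol this models).
#' @return Object of class `dose_color_record` with the per-channel
#'   arithmetic `mean_color`.
#' @export
dose_color_record <- function(dose, replicates) {
  stopifnot(is.numeric(dose), length(dose) == 1L, dose >= 0)
  if (inherits(replicates, "lab_color")) replicates <- list(replicates)
  if (!length(replicates) || !all(vapply(replicates, inherits, logical(1), "lab_color")))
    stop("`replicates` must be a non-empty list of lab_color objects")
  mean_color <- lab_color(mean(vapply(replicates, `[[`, numeric(1), "L")),
                          mean(vapply(replicates, `[[`, numeric(1), "a")),
                          mean(vapply(replicates, `[[`, numeric(1), "b")))
  structure(list(dose = dose, replicates = replicates, mean_color = mean_color),
            class = "dose_color_record")
}

#' CIE76 total colour difference
#'
#' \eqn{\Delta E = \sqrt{(\Delta L^*)^2 + (\Delta a^*)^2 + (\Delta b^*)^2}}.
#'
#' @param c1,c2 [lab_color()] objects.
#' @return Non-negative dimensionless difference.
#' @export
delta_e <- function(c1, c2) {
  stopifnot(inherits(c1, "lab_color"), inherits(c2, "lab_color"))
  sqrt((c1$L - c2$L)^2 + (c1$a - c2$a)^2 + (c1$b - c2$b)^2)
}

#' Verbal classification of a colour difference
#'
#' The conventional visibility scale: \[0, 1) "normally invisible", \[1, 2)
#' "very small" (obvious only to a trained eye), \[2, 3.5) "medium" (obvious
#' also to an untrained eye), \[3.5, 5\] "obvious", and above 5 "very
#' obvious". A value of exactly 5 classifies as "obvious".
#'
#' @param value Non-negative colour difference(s).
#' @return Character vector of category labels.
#' @export
classify_delta_e <- function(value) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("colour differences must be non-negative")
  cut(value, breaks = c(-Inf, 1, 2, 3.5, 5, Inf), right = FALSE,
      labels = c("normally invisible", "very small", "medium", "obvious",
                 "very obvious")) |>
    as.character() |>
    (\(lab) ifelse(value == 5, "obvious", lab))()
}

#' Dose series of colour differences
#'
#' Colour difference of every dose's mean colour against the reference dose's
#' mean colour, with the verbal category and a monotonicity flag (does
#' \eqn{\Delta E} increase with dose?).
#'
#' @param records List of [dose_color_record()] objects.
#' @param reference_dose Dose used as the comparison basis (default 0 kGy);
#'   must be present in `records`.
#' @return List with `table` (data frame: `dose`, `delta_e`, `category`) and
#'   logical `monotone_increasing`.
#' @export
dose_series_report <- function(records, reference_dose = 0) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "dose_color_record")))
  doses <- vapply(records, `[[`, numeric(1), "dose")
  iref <- which(doses == reference_dose)
  if (!length(iref)) stop("reference dose ", reference_dose, " kGy not present")
  ref <- records[[iref[1]]]$mean_color
  o <- order(doses)
  de <- vapply(records[o], function(r) delta_e(r$mean_color, ref), numeric(1))
  tab <- data.frame(dose = doses[o], delta_e = de,
                    category = classify_delta_e(de))
  list(table = tab, monotone_increasing = !is.unsorted(de))
}

#' Read a delimited colour table
#'
#' CSV with columns `dose_kGy`, `L`, `a`, `b` and optionally `replicate`;
#' rows sharing a dose become replicates of one record.
#'
#' @param path File path.
#' @return List of [dose_color_record()] objects.
#' @export
read_color_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("dose_kGy", "L", "a", "b") %in% names(d)))
    stop("colour table must have columns dose_kGy, L, a, b")
  lapply(split(d, d$dose_kGy), function(g)
    dose_color_record(g$dose_kGy[1],
                      lapply(seq_len(nrow(g)), function(i)
                        lab_color(g$L[i], g$a[i], g$b[i]))))
}
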