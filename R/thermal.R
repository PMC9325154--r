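#' Melting-point records per dose
#'
#' Bookkeeping for capillary and DSC melting points across absorbed doses.
#'
#' @param dose Absorbed doses in kGy.
#' @param capillary_mp Capillary melting points in Celsius (NA allowed).
#' @param dsc_mp DSC melting points in Celsius (NA allowed).
#' @return Object of class `melting_records` (a data frame).
#' @export
melting_records <- function(dose, capillary_mp = NA_real_, dsc_mp = NA_real_) {
  d <- data.frame(dose = dose, capillary_mp = capillary_mp, dsc_mp = dsc_mp)
  if (any(duplicated(d$dose))) stop("duplicated doses in melting records")
  class(d) <- c("melting_records", "data.frame")
  d
}

#' Melting-point shift between two doses
#'
#' `mp(dose_a) - mp(dose_b)` for the chosen method; a positive value with
#' `dose_a` the unirradiated sample is a radiation-induced decrease.
#'
#' @param records A [melting_records()] table.
#' @param method `"capillary"` or `"dsc"`.
#' @param dose_a,dose_b Doses to compare (both must be present).
#' @return Shift in Celsius.
#' @export
melting_shift <- function(records, method = c("capillary", "dsc"), dose_a, dose_b) {
  method <- match.arg(method)
  stopifnot(inherits(records, "melting_records"))
  col <- if (method == "capillary") "capillary_mp" else "dsc_mp"
  ia <- which(records$dose == dose_a); ib <- which(records$dose == dose_b)
  if (!length(ia)) stop("dose ", dose_a, " kGy not present in the records")
  if (!length(ib)) stop("dose ", dose_b, " kGy not present in the records")
  va <- records[[col]][ia[1]]; vb <- records[[col]][ib[1]]
  if (is.na(va) || is.na(vb)) stop("melting point missing for the requested dose/method")
  va - vb
}

#' DSC thermogram
#'
#' @param temperature Temperatures in Celsius, strictly increasing.
#' @param heat_flow Heat-flow signal (a.u.).
#' @return Object of class `thermogram`.
#' @export
thermogram <- function(temperature, heat_flow) {
  stopifnot(is.numeric(temperature), is.numeric(heat_flow))
  if (length(temperature) != length(heat_flow))
    stop("`temperature` and `heat_flow` lengths differ")
  if (is.unsorted(temperature, strictly = TRUE))
    stop("`temperature` must be strictly increasing")
  structure(list(temperature = temperature, heat_flow = heat_flow),
            class = "thermogram")
}

#' Characterize a DSC endotherm
#'
#' Locates the dominant peak in `region`, computes its area above the
#' straight line joining the region endpoints (linear baseline correction)
#' and the extrapolated onset: the tangent at the maximum rising slope
#' intersected with the pre-peak linear baseline. A region whose peak does
#' not stand clear of the endpoint baseline returns `found = FALSE`.
#'
#' @param tg A [thermogram()].
#' @param region Optional temperature interval in Celsius; default the whole
#'   trace.
#' @return List with `found`, `peak_temperature` (C), `onset` (C) and `area`
#'   (a.u. x C, above the linear baseline).
#' @export
dsc_peak <- function(tg, region = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  idx <- if (is.null(region)) seq_along(tg$temperature)
         else which(tg$temperature >= region[1] & tg$temperature <= region[2])
  if (length(idx) < 5L) stop("region contains too few points")
  x <- tg$temperature[idx]; y <- tg$heat_flow[idx]
  n <- length(x)
  base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  d <- y - base
  ip <- which.max(abs(d))
  # peak must stand clear of the residual wiggle at the region ends
  edge <- c(d[seq_len(max(3L, n %/% 20))], d[seq(n - max(3L, n %/% 20) + 1L, n)])
  if (abs(d[ip]) < 10 * max(stats::sd(edge), 1e-12) || ip %in% c(1L, n))
    return(list(found = FALSE, peak_temperature = NA_real_, onset = NA_real_,
                area = NA_real_))
  sgn <- sign(d[ip])
  area <- pracma::trapz(x, sgn * d)
  # onset: steepest slope on the leading edge, tangent intersected with the
  # pre-peak baseline
  lead <- seq_len(ip)
  slopes <- diff(sgn * d[lead]) / diff(x[lead])
  im <- which.max(slopes)
  xm <- (x[im] + x[im + 1L]) / 2
  ym <- (sgn * d[im] + sgn * d[im + 1L]) / 2
  onset <- xm - ym / slopes[im]
  list(found = TRUE, peak_temperature = x[ip], onset = onset, area = area)
}

#' Read a delimited thermogram
#'
#' Two-column CSV (`temperature_C`, `heat_flow`) with a header row.
#'
#' @param path File path.
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("temperature_C", "heat_flow") %in% names(d)))
    stop("thermogram table must have columns temperature_C, heat_flow")
  thermogram(d$temperature_C, d$heat_flow)
}
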