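#' Construct a drying curve
#'
#' A drying curve is a time-ordered record of dry-basis moisture content
#' during thin-layer drying, together with the metadata needed to normalize
#' it to a moisture ratio: the initial moisture `x0`, the equilibrium
#' moisture `xe` and the drying air temperature.
#'
#' Moisture here is always dry basis (water mass per dry-matter mass),
#' expressed as a decimal fraction, and time is in hours: drying constants
#' of the thin-layer models are conventionally reported in h^-1.
#'
#' @param time_h numeric vector of sampling times in hours, strictly
#'   increasing, starting at 0.
#' @param moisture_db dry-basis moisture (decimal fraction in (0, 1)),
#'   same length as `time_h`.
#' @param x0 initial moisture content (d.b. decimal). The first value of
#'   `moisture_db` must agree with `x0` within `tol`.
#' @param xe equilibrium moisture content (d.b. decimal), or `NULL` if
#'   unknown (see [moisture_ratio()] for the fallback policy). When given
#'   it must lie below every observed moisture.
#' @param air_temp_C drying air temperature in degrees Celsius (metadata).
#' @param label free-text label.
#' @param tol tolerance for the `moisture_db[1] == x0` check; defaults to
#'   0.02 (absolute, d.b. decimal) to accommodate measurement noise.
#'
#' @return An object of class `drying_curve`: a list with the validated
#'   fields above.
#' @examples
#' dc <- drying_curve(time_h = c(0, 0.5, 1), moisture_db = c(0.23, 0.18, 0.15),
#'                    x0 = 0.23, xe = 0.05, air_temp_C = 80)
#' moisture_ratio(dc)
#' @export
drying_curve <- function(time_h, moisture_db, x0, xe = NULL,
                         air_temp_C = NA_real_, label = "", tol = 0.02) {
  check_numeric(time_h, "time_h")
  check_numeric(moisture_db, "moisture_db")
  if (length(time_h) != length(moisture_db)) {
    stop_contract("`time_h` and `moisture_db` must have the same length")
  }
  if (time_h[1] != 0) stop_contract("`time_h` must start at 0")
  if (length(time_h) > 1 && any(diff(time_h) <= 0)) {
    stop_contract("`time_h` must be strictly increasing")
  }
  if (any(moisture_db <= 0) || any(moisture_db >= 1)) {
    stop_contract("`moisture_db` values must lie in (0, 1) (d.b. decimal)")
  }
  stopifnot(is.numeric(x0), length(x0) == 1, x0 > 0, x0 < 1)
  if (abs(moisture_db[1] - x0) > tol) {
    stop_contract("first moisture value (", moisture_db[1],
                  ") does not match x0 (", x0, ") within tolerance ", tol)
  }
  if (!is.null(xe)) {
    stopifnot(is.numeric(xe), length(xe) == 1, xe >= 0)
    if (xe >= min(moisture_db)) {
      stop_contract("xe (", xe, ") must lie below all observed moisture values")
    }
  }
  structure(
    list(time_h = as.numeric(time_h), moisture_db = as.numeric(moisture_db),
         x0 = as.numeric(x0), xe = if (is.null(xe)) NULL else as.numeric(xe),
         air_temp_C = as.numeric(air_temp_C), label = as.character(label)),
    class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat("Drying curve", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat(sprintf("  %d points over %.3g h; x0 = %.4g, xe = %s, air %.4g degC\n",
              length(x$time_h), max(x$time_h), x$x0,
              if (is.null(x$xe)) "unset" else format(x$xe), x$air_temp_C))
  invisible(x)
}

#' Moisture ratio of a drying curve
#'
#' Normalizes a dry-basis moisture record to the dimensionless moisture
#' ratio `MR = (X - Xe) / (X0 - Xe)`, which equals 1 at the start of drying
#' and tends to 0 as the grain approaches equilibrium with the drying air.
#'
#' If the curve carries no equilibrium moisture `xe`, a fallback of
#' `0.9 * min(moisture_db)` is used and a warning is issued; the fallback
#' keeps MR strictly positive without assuming a sorption isotherm, but a
#' measured or isotherm-derived `xe` should be preferred. Observed moisture
#' at or below `xe` (possible in noisy tails) is clipped to MR = 0 with a
#' warning rather than producing negative ratios.
#'
#' @param curve a [drying_curve()].
#' @return An object of class `mr_series`: a data frame with columns
#'   `time_h` and `mr`.
#' @export
moisture_ratio <- function(curve) {
  stopifnot(inherits(curve, "drying_curve"))
  xe <- curve$xe
  if (is.null(xe)) {
    xe <- 0.9 * min(curve$moisture_db)
    warning("no equilibrium moisture supplied; using fallback xe = 0.9 * min(moisture) = ",
            signif(xe, 4), call. = FALSE)
  }
  if (curve$x0 <= xe) {
    stop_contract("x0 (", curve$x0, ") must exceed xe (", xe, ")")
  }
  mr <- (curve$moisture_db - xe) / (curve$x0 - xe)
  if (any(mr < 0)) {
    warning(sum(mr < 0), " moisture value(s) below xe; clipping MR to 0",
            call. = FALSE)
    mr[mr < 0] <- 0
  }
  mr_series(curve$time_h, mr)
}

#' Construct a moisture-ratio series
#'
#' @param time_h sampling times (hours), strictly increasing from 0.
#' @param mr dimensionless moisture ratio, same length. Values slightly
#'   outside \[0, 1\] (up to 0.05) are tolerated for noisy data.
#' @return A data frame of class `mr_series` with columns `time_h`, `mr`.
#' @export
mr_series <- function(time_h, mr) {
  check_numeric(time_h, "time_h")
  check_numeric(mr, "mr")
  if (length(time_h) != length(mr)) {
    stop_contract("`time_h` and `mr` must have the same length")
  }
  if (length(time_h) > 1 && any(diff(time_h) <= 0)) {
    stop_contract("`time_h` must be strictly increasing")
  }
  if (any(mr < -0.05) || any(mr > 1.05)) {
    stop_contract("`mr` values must lie in [-0.05, 1.05]")
  }
  structure(data.frame(time_h = as.numeric(time_h), mr = as.numeric(mr)),
            class = c("mr_series", "data.frame"))
}
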