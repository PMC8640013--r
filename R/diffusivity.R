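# Effective moisture diffusivity from the analytical solution of Fick's
# second law for a sphere, and Arrhenius analysis of its temperature
# dependence.
#
# For a sphere of radius R (m) with uniform initial moisture, symmetric
# center condition and surface held at the equilibrium moisture, the
# moisture ratio follows the series
#
#   MR(t) = (6 / pi^2) * sum_{n>=1} (1/n^2) exp(-D n^2 pi^2 t / R^2)
#
# with t in seconds and D the effective diffusivity (m^2 s^-1). Times are
# converted from hours to seconds at this boundary; the drying-model layer
# stays in hours.

#' Universal gas constant in J kmol^-1 K^-1
#' @export
GAS_CONSTANT_J_KMOL_K <- 8314

#' Fick-sphere moisture ratio series
#'
#' Evaluates the truncated analytical series solution of Fick's second
#' law for a sphere. At `t = 0` the truncated series returns
#' `(6/pi^2) * sum_{n<=N} 1/n^2`, which approaches 1 as the truncation
#' order N grows; the deviation from 1 is bounded by `6 / (pi^2 N)`.
#'
#' @param d_m2s effective diffusivity (m^2 s^-1), positive.
#' @param radius_m equivalent sphere radius (m), positive.
#' @param t_s times in seconds, non-negative.
#' @param n_terms series truncation order (>= 1). 50 terms are ample for
#'   fitting at t > 0; use more (e.g. 1000) when generating values near
#'   t = 0.
#' @return Moisture ratio at each time.
#' @export
fick_sphere_mr <- function(d_m2s, radius_m, t_s, n_terms = 50) {
  stopifnot(is.numeric(d_m2s), length(d_m2s) == 1, d_m2s > 0,
            is.numeric(radius_m), length(radius_m) == 1, radius_m > 0)
  check_numeric(t_s, "t_s")
  if (any(t_s < 0)) stop_contract("times must be non-negative")
  if (!is.numeric(n_terms) || n_terms < 1) stop_contract("n_terms must be >= 1")
  n <- seq_len(as.integer(n_terms))
  rate <- d_m2s * pi^2 / radius_m^2
  # terms: exp(-rate * n^2 * t) / n^2, summed over n for each t
  E <- exp(-outer(n^2, t_s, function(nn, tt) rate * nn * tt))
  as.numeric(6 / pi^2 * colSums(E / n^2))
}

#' Equivalent sphere radius from grain axes
#'
#' Radius of the sphere with the same volume as a triaxial grain:
#' `(a b c)^(1/3) / 2`, with axes in mm and the result in metres.
#'
#' @inheritParams grain_volume
#' @return Equivalent radius in metres.
#' @export
equivalent_radius_m <- function(a_mm, b_mm, c_mm) {
  (a_mm * b_mm * c_mm)^(1 / 3) / 2 / 1000
}

#' Effective diffusivity by the method of slopes
#'
#' In the first-term regime of the Fick-sphere series, `ln(MR)` is linear
#' in time with slope `-D pi^2 / R^2`. The method of slopes regresses
#' `ln(MR)` on time over the observations with `0 < MR < mr_max`
#' (default 0.6, below which the first term dominates) and converts the
#' slope to a diffusivity.
#'
#' @param mr an [mr_series()] (times in hours) or a data frame with
#'   columns `time_h` and `mr`.
#' @param radius_m equivalent sphere radius (m).
#' @param mr_max upper end of the regression window (default 0.6).
#' @return An object of class `diffusivity_estimate`: list with `d_m2s`,
#'   `method = "slopes"`, `radius_m`, `n_terms = 1`, `fit_r2_pct`,
#'   `n_used`.
#' @export
estimate_d_slopes <- function(mr, radius_m, mr_max = 0.6) {
  stopifnot(is.data.frame(mr), all(c("time_h", "mr") %in% names(mr)),
            is.numeric(radius_m), radius_m > 0)
  use <- mr$mr > 0 & mr$mr < mr_max
  if (sum(use) < 3) {
    stop_contract("need at least 3 observations with 0 < MR < ", mr_max)
  }
  t_s <- mr$time_h[use] * 3600
  lmr <- log(mr$mr[use])
  fit <- stats::lm(lmr ~ t_s)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop_contract("non-negative ln(MR) slope: data do not describe drying")
  }
  d <- -slope * radius_m^2 / pi^2
  r2 <- suppressWarnings(100 * summary(fit)$r.squared)
  structure(list(d_m2s = d, method = "slopes", radius_m = radius_m,
                 n_terms = 1L, fit_r2_pct = r2,
                 n_used = sum(use)),
            class = "diffusivity_estimate")
}

#' Effective diffusivity by full-series least squares
#'
#' One-parameter bounded minimization of the SSE between observed
#' moisture ratios and the truncated Fick-sphere series, searched over
#' `log10(D)` for conditioning with D in \[1e-13, 1e-7\] m^2 s^-1.
#'
#' @inheritParams estimate_d_slopes
#' @param n_terms series truncation used during fitting (default 50).
#' @param d_bounds search interval for D (m^2 s^-1).
#' @return A `diffusivity_estimate` with `method = "series_fit"` and the
#'   R^2 (percent) of observed vs fitted MR; `converged` is FALSE when
#'   the optimum sits at the edge of `d_bounds`.
#' @export
estimate_d_series <- function(mr, radius_m, n_terms = 50,
                              d_bounds = c(1e-13, 1e-7)) {
  stopifnot(is.data.frame(mr), all(c("time_h", "mr") %in% names(mr)),
            is.numeric(radius_m), radius_m > 0)
  if (nrow(mr) == 0) stop_contract("empty moisture-ratio series")
  t_s <- mr$time_h * 3600
  obs <- mr$mr
  sse <- function(ld) sum((obs - fick_sphere_mr(10^ld, radius_m, t_s, n_terms))^2)
  opt <- stats::optimize(sse, interval = log10(d_bounds), tol = 1e-10)
  d <- 10^opt$minimum
  edge <- min(opt$minimum - log10(d_bounds[1]),
              log10(d_bounds[2]) - opt$minimum) < 1e-6
  fitted <- fick_sphere_mr(d, radius_m, t_s, n_terms)
  r2 <- if (stats::var(obs) > 0) r_squared(obs, fitted) else NA_real_
  structure(list(d_m2s = d, method = "series_fit", radius_m = radius_m,
                 n_terms = as.integer(n_terms), fit_r2_pct = r2,
                 n_used = length(obs), converged = !edge),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("<diffusivity_estimate> D = %.4g m^2/s (%s, R = %.3g mm, R2 = %.2f%%)\n",
              x$d_m2s, x$method, 1000 * x$radius_m, x$fit_r2_pct))
  invisible(x)
}

#' Arrhenius fit of diffusivity against temperature
#'
#' Fits `D = A exp(-E / (R T))` by ordinary linear regression of `ln(D)`
#' on `1/T`: the activation energy is `E = -slope * R` and the
#' pre-exponential constant is `A = exp(intercept)`. The gas constant is
#' 8314 J kmol^-1 K^-1, so E is reported in kJ kmol^-1.
#'
#' @param t_k absolute temperatures (K), at least 2 distinct values.
#' @param d_m2s effective diffusivities (m^2 s^-1), positive, same length.
#' @return An object of class `arrhenius_fit`: list with `a_m2s`,
#'   `e_kj_kmol`, `gas_const` (J kmol^-1 K^-1), `r2_pct` and the input
#'   `points`.
#' @examples
#' af <- arrhenius_fit(c(353.15, 373.15, 393.15), c(1e-10, 2e-10, 4e-10))
#' af$e_kj_kmol
#' @export
arrhenius_fit <- function(t_k, d_m2s) {
  check_numeric(t_k, "t_k"); check_numeric(d_m2s, "d_m2s")
  if (length(t_k) != length(d_m2s)) stop_contract("`t_k` and `d_m2s` lengths differ")
  if (any(t_k <= 0)) stop_contract("temperatures must be positive (K)")
  if (any(d_m2s <= 0)) stop_contract("diffusivities must be positive")
  if (length(unique(t_k)) < 2) {
    stop_contract("need at least 2 distinct temperatures")
  }
  inv_t <- 1 / t_k
  fit <- stats::lm(log(d_m2s) ~ inv_t)
  co <- stats::coef(fit)
  e_j_kmol <- -unname(co[2]) * GAS_CONSTANT_J_KMOL_K
  r2 <- if (stats::var(log(d_m2s)) > 0)
    suppressWarnings(100 * summary(fit)$r.squared) else 100
  structure(list(a_m2s = exp(unname(co[1])), e_kj_kmol = e_j_kmol / 1000,
                 gas_const = GAS_CONSTANT_J_KMOL_K,
                 r2_pct = r2,
                 points = data.frame(t_k = t_k, d_m2s = d_m2s)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> A = %.4g m^2/s, E = %.4g kJ/kmol (%d points)\n",
              x$a_m2s, x$e_kj_kmol, nrow(x$points)))
  invisible(x)
}
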