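# Registry of the classical semi-empirical thin-layer drying models.
#
# Each model maps drying time t (hours) to the dimensionless moisture ratio
# MR. Drying constants k, k0, k1 are in h^-1; a, b, c, n are dimensionless
# empirical coefficients. All formulas are the forms conventional in the
# thin-layer drying literature:
#
#   newton                    MR = exp(-k t)
#   page                      MR = exp(-k t^n)
#   page_modified             MR = exp(-(k t)^n)
#   henderson_pabis           MR = a exp(-k t)
#   logarithmic               MR = a exp(-k t) + c
#   two_terms                 MR = a exp(-k0 t) + b exp(-k1 t)
#   two_exponential_terms     MR = a exp(-k t) + (1 - a) exp(-k a t)
#   wang_singh                MR = 1 + a t + b t^2
#   henderson_pabis_modified  MR = a exp(-k t) + b exp(-k0 t) + c exp(-k1 t)
#   midilli                   MR = a exp(-k t^n) + b t
#   diffusion_approximation   MR = a exp(-k t) + (1 - a) exp(-k b t)

# crude k estimate: slope of -ln(y) on t over the decaying part of the curve
.init_k <- function(t, y) {
  ok <- y > 1e-8 & t > 0
  if (sum(ok) >= 2) {
    s <- stats::coef(stats::lm(I(-log(y[ok])) ~ t[ok]))[2]
    if (is.finite(s) && s > 1e-6) return(unname(s))
  }
  0.5
}

.K_BOUNDS <- c(1e-6, 1e3)   # k, k0, k1 (h^-1)
.N_BOUNDS <- c(1e-6, 10)    # Page exponent
.C_BOUNDS <- c(-100, 100)   # a, b, c coefficients

.drying_registry <- local({
  kb <- .K_BOUNDS; nb <- .N_BOUNDS; cb <- .C_BOUNDS
  list(
    newton = list(
      params = "k", lower = kb[1], upper = kb[2],
      fn = function(p, t) exp(-p[["k"]] * t),
      init = function(t, y) c(k = .init_k(t, y))),
    page = list(
      params = c("k", "n"), lower = c(kb[1], nb[1]), upper = c(kb[2], nb[2]),
      fn = function(p, t) exp(-p[["k"]] * t^p[["n"]]),
      init = function(t, y) c(k = .init_k(t, y), n = 1)),
    page_modified = list(
      params = c("k", "n"), lower = c(kb[1], nb[1]), upper = c(kb[2], nb[2]),
      fn = function(p, t) exp(-(p[["k"]] * t)^p[["n"]]),
      init = function(t, y) c(k = .init_k(t, y), n = 1)),
    henderson_pabis = list(
      params = c("a", "k"), lower = c(cb[1], kb[1]), upper = c(cb[2], kb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k"]] * t),
      init = function(t, y) c(a = 1, k = .init_k(t, y))),
    logarithmic = list(
      params = c("a", "k", "c"),
      lower = c(cb[1], kb[1], cb[1]), upper = c(cb[2], kb[2], cb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k"]] * t) + p[["c"]],
      init = function(t, y) c(a = 1, k = .init_k(t, y), c = 0)),
    two_terms = list(
      params = c("a", "k0", "b", "k1"),
      lower = c(cb[1], kb[1], cb[1], kb[1]),
      upper = c(cb[2], kb[2], cb[2], kb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k0"]] * t) + p[["b"]] * exp(-p[["k1"]] * t),
      init = function(t, y) {
        k <- .init_k(t, y)
        c(a = 0.5, k0 = k, b = 0.5, k1 = 2 * k)
      }),
    two_exponential_terms = list(
      params = c("a", "k"), lower = c(cb[1], kb[1]), upper = c(cb[2], kb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k"]] * t) +
        (1 - p[["a"]]) * exp(-p[["k"]] * p[["a"]] * t),
      init = function(t, y) c(a = 1.5, k = .init_k(t, y))),
    wang_singh = list(
      params = c("a", "b"), lower = c(cb[1], cb[1]), upper = c(cb[2], cb[2]),
      fn = function(p, t) 1 + p[["a"]] * t + p[["b"]] * t^2,
      init = function(t, y) {
        # quadratic through MR(0) = 1 has an exact least-squares start
        if (length(t) >= 3 && stats::var(t) > 0) {
          co <- tryCatch(stats::coef(stats::lm(I(y - 1) ~ 0 + t + I(t^2))),
                         error = function(e) c(-0.3, 0.01))
          c(a = unname(co[1]), b = unname(co[2]))
        } else c(a = -0.3, b = 0.01)
      }),
    henderson_pabis_modified = list(
      params = c("a", "k", "b", "k0", "c", "k1"),
      lower = c(cb[1], kb[1], cb[1], kb[1], cb[1], kb[1]),
      upper = c(cb[2], kb[2], cb[2], kb[2], cb[2], kb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k"]] * t) +
        p[["b"]] * exp(-p[["k0"]] * t) + p[["c"]] * exp(-p[["k1"]] * t),
      init = function(t, y) {
        k <- .init_k(t, y)
        c(a = 1 / 3, k = k, b = 1 / 3, k0 = 2 * k, c = 1 / 3, k1 = 0.5 * k)
      }),
    midilli = list(
      params = c("a", "k", "n", "b"),
      lower = c(cb[1], kb[1], nb[1], cb[1]),
      upper = c(cb[2], kb[2], nb[2], cb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) + p[["b"]] * t,
      init = function(t, y) c(a = 1, k = .init_k(t, y), n = 1, b = 0)),
    diffusion_approximation = list(
      params = c("a", "k", "b"),
      lower = c(cb[1], kb[1], cb[1]), upper = c(cb[2], kb[2], cb[2]),
      fn = function(p, t) p[["a"]] * exp(-p[["k"]] * t) +
        (1 - p[["a"]]) * exp(-p[["k"]] * p[["b"]] * t),
      init = function(t, y) c(a = 0.5, k = .init_k(t, y), b = 2))
  )
})

#' Names of the registered thin-layer drying models
#'
#' @return Character vector of the eleven registered model names.
#' @export
drying_models <- function() names(.drying_registry)

#' Retrieve a thin-layer drying model specification
#'
#' Returns the closed-form specification of one of the eleven registered
#' thin-layer drying models: its parameter names, box bounds used during
#' fitting, a default-initialization rule and the vectorized model
#' function itself. The bounds are wide boxes bracketing parameter
#' estimates typically reported for cereal and oilseed drying
#' (`k, k0, k1` in (1e-6, 1e3) h^-1, `n` in (1e-6, 10), coefficients
#' `a, b, c` in (-100, 100)).
#'
#' @param name one of [drying_models()].
#' @return An object of class `model_spec` with fields `name`, `params`,
#'   `lower`, `upper`, `fn(params, t)` and `init(t, y)`.
#' @examples
#' spec <- drying_model("newton")
#' evaluate_model(spec, c(k = 0.46), t = c(0, 1, 2))
#' @export
drying_model <- function(name) {
  name <- match.arg(name, drying_models())
  m <- .drying_registry[[name]]
  structure(list(name = name, kind = "drying", params = m$params,
                 lower = stats::setNames(m$lower, m$params),
                 upper = stats::setNames(m$upper, m$params),
                 fn = m$fn, init = m$init),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s): %s\n", x$name, x$kind,
              paste(x$params, collapse = ", ")))
  invisible(x)
}

#' Evaluate a registered model at given predictor values
#'
#' Exact closed-form evaluation of a drying model (predictor: time in
#' hours) or shrinkage model (predictor: dry-basis moisture), vectorized
#' over the predictor.
#'
#' @param spec a `model_spec` from [drying_model()] or [shrinkage_model()].
#' @param params named vector or list supplying exactly the parameters of
#'   `spec` (extra or missing names are an error).
#' @param t predictor values; for drying models these are times (h) and
#'   must be non-negative.
#' @return Numeric vector of model values (moisture ratio or unit
#'   volumetric shrinkage), same length as `t`.
#' @export
evaluate_model <- function(spec, params, t) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as_param_vector(params)
  if (!setequal(names(p), spec$params) || length(p) != length(spec$params)) {
    stop_contract("model '", spec$name, "' needs exactly parameters {",
                  paste(spec$params, collapse = ", "), "}; got {",
                  paste(names(p), collapse = ", "), "}")
  }
  check_numeric(t, "t")
  if (spec$kind == "drying" && any(t < 0)) {
    stop_contract("drying time must be non-negative")
  }
  if (!is.null(spec$domain)) spec$domain(as.list(p), t)
  as.numeric(spec$fn(as.list(p), t))
}
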