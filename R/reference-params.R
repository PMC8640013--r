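# Reference fitted parameter sets for soybean thin-layer drying and
# volumetric shrinkage, as published for a continuous-dryer experiment at
# 80, 100 and 120 deg C air temperature with lots harvested at 23% and
# 18% (d.b.) initial moisture. They serve as realistic generating values
# for parameter-recovery exercises and as defaults in examples. The sets
# are carried verbatim as published, including entries that are
# typographically dubious (some shrinkage rows interleave coefficients or
# omit one, and a few evaluate outside the physical psi range); no
# reassignment between rows is attempted, and validation is left to the
# consuming code.

.ref_row <- function(harvest, temp, model, ...) {
  p <- c(...)
  data.frame(harvest_moisture_pct = harvest, air_temp_C = temp,
             model = model, param = names(p), value = unname(p),
             stringsAsFactors = FALSE)
}

.drying_ref <- local({
  r <- .ref_row
  do.call(rbind, list(
    # 23% (d.b.) initial moisture
    r(23, 80, "newton", k = 0.463600),
    r(23, 100, "newton", k = 0.662870),
    r(23, 120, "newton", k = 7.602332),
    r(23, 80, "page", k = 0.293530, n = 1.617070),
    r(23, 100, "page", k = 0.388050, n = 1.302200),
    r(23, 120, "page", k = 0.499964, n = 0.000125),
    r(23, 80, "page_modified", k = 0.468590, n = 1.617070),
    r(23, 100, "page_modified", k = 0.665160, n = 1.302200),
    r(23, 120, "page_modified", k = 0.046526, n = 0.000017),
    r(23, 80, "henderson_pabis", a = 1.064980, k = 0.488950),
    r(23, 100, "henderson_pabis", a = 1.047710, k = 0.699440),
    r(23, 120, "henderson_pabis", a = 0.989430, k = 7.531181),
    r(23, 80, "logarithmic", a = 11.168900, k = 0.024820, c = -10.189600),
    r(23, 100, "logarithmic", a = 2.704230, k = 0.157990, c = -1.732700),
    r(23, 120, "logarithmic", a = 0.930360, k = 9.952775, c = 0.067291),
    r(23, 80, "two_terms", a = 0.532496, k0 = 0.498886, b = 0.532496, k1 = 0.498860),
    r(23, 100, "two_terms", a = 0.523857, k0 = 0.699442, b = 0.523557, k1 = 0.699442),
    r(23, 120, "two_terms", a = 0.494720, k0 = 7.531181, b = 0.494720, k1 = 7.531181),
    r(23, 80, "two_exponential_terms", a = 1.938070, k = 0.726790),
    r(23, 100, "two_exponential_terms", a = 1.796970, k = 0.955320),
    r(23, 120, "two_exponential_terms", a = 0.317576, k = 17.995330),
    r(23, 80, "wang_singh", a = -0.284900, b = 0.002680),
    r(23, 100, "wang_singh", a = -0.462100, b = 0.039562),
    r(23, 120, "wang_singh", a = -4.089220, b = 4.080789),
    r(23, 80, "henderson_pabis_modified",
      a = 0.354997, k = 0.498886, b = 0.354997, k0 = 0.198886,
      c = 0.354997, k1 = 0.498886),
    r(23, 100, "henderson_pabis_modified",
      a = 0.349238, k = 0.699442, b = 0.349238, k0 = 0.699442,
      c = 0.349238, k1 = 0.699442),
    r(23, 120, "henderson_pabis_modified",
      a = 0.329811, k = 7.531181, b = 0.329811, k0 = 7.531181,
      c = 0.329811, k1 = 7.531181),
    r(23, 80, "midilli", a = 0.990558, k = 0.023506, n = 0.000019, b = -0.264911),
    r(23, 100, "midilli", a = 1.003716, k = 0.175032, n = 0.519332, b = -0.268476),
    r(23, 120, "midilli", a = 0.771639, k = 0.626056, n = 0.000218, b = -0.684975),
    r(23, 80, "diffusion_approximation", a = 0.541710, k = 0.464301, b = 1.000000),
    r(23, 100, "diffusion_approximation", a = 0.528730, k = 0.662866, b = 0.999900),
    r(23, 120, "diffusion_approximation", a = 0.409782, k = 9.255399, b = 55.000000),
    # 18% (d.b.) initial moisture
    r(18, 80, "newton", k = 0.971060),
    r(18, 100, "newton", k = 5.889470),
    r(18, 120, "newton", k = 5.786360),
    r(18, 80, "page", k = 0.974770, n = 0.976759),
    r(18, 100, "page", k = 0.620970, n = 0.000086),
    r(18, 120, "page", k = 0.672511, n = 0.000004),
    r(18, 80, "page_modified", k = 0.974180, n = 0.976759),
    r(18, 100, "page_modified", k = 0.044058, n = 0.000038),
    r(18, 120, "page_modified", k = 0.044463, n = 0.000079),
    r(18, 80, "henderson_pabis", a = 0.955030, k = 0.924030),
    r(18, 100, "henderson_pabis", a = 0.970820, k = 5.691402),
    r(18, 120, "henderson_pabis", a = 1.001650, k = 5.793869),
    r(18, 80, "logarithmic", a = 1.430271, k = 0.405995, c = -0.534078),
    r(18, 100, "logarithmic", a = 0.912190, k = 8.981745, c = 0.081508),
    r(18, 120, "logarithmic", a = 1.071784, k = 4.830920, c = -0.076094),
    r(18, 80, "two_terms", a = 0.477517, k0 = 0.924032, b = 0.477517, k1 = 0.924032),
    r(18, 100, "two_terms", a = 0.485410, k0 = 5.691402, b = 0.485410, k1 = 5.691402),
    r(18, 120, "two_terms", a = 0.500825, k0 = 5.753869, b = 0.500825, k1 = 5.793869),
    r(18, 80, "two_exponential_terms", a = 1.390710, k = 1.090440),
    r(18, 100, "two_exponential_terms", a = 0.291287, k = 14.968630),
    r(18, 120, "two_exponential_terms", a = 1.481680, k = 6.748937),
    r(18, 80, "wang_singh", a = -0.718800, b = 0.132126),
    r(18, 100, "wang_singh", a = -2.820600, b = 1.925448),
    r(18, 120, "wang_singh", a = -4.050820, b = 4.181176),
    r(18, 80, "henderson_pabis_modified",
      a = 0.318345, k = 0.924032, b = 0.318345, k0 = 0.924032,
      c = 0.318345, k1 = 0.924032),
    r(18, 100, "henderson_pabis_modified",
      a = 0.323610, k = 5.691402, b = 0.323610, k0 = 5.691402,
      c = 0.323610, k1 = 5.691402),
    r(18, 120, "henderson_pabis_modified",
      a = 0.333883, k = 5.793869, b = 0.333883, k0 = 5.793869,
      c = 0.333883, k1 = 5.793869),
    r(18, 80, "midilli", a = 0.945430, k = 0.190295, n = 0.000044, b = -0.345100),
    r(18, 100, "midilli", a = 0.785988, k = 0.511196, n = 0.000012, b = 0.610212),
    r(18, 120, "midilli", a = 1.000000, k = 1.329180, n = 0.373421, b = 0.716832),
    r(18, 80, "diffusion_approximation", a = 0.569273, k = 0.971060, b = 1.000000),
    r(18, 100, "diffusion_approximation", a = 0.414057, k = 2.257450, b = 1.032470),
    r(18, 120, "diffusion_approximation", a = 9.285317, k = 7.678640, b = 1.039170)
  ))
})

# shrinkage reference sets, 23% (d.b.) harvest. Published per-condition
# coefficient pairs; the lang_sokhansanj 80 deg C row carries a single
# coefficient and the rahman 100/120 deg C rows only the intercept, as
# published.
.shrinkage_ref <- local({
  r <- .ref_row
  do.call(rbind, list(
    r(23, 80, "bala_woods", a = 0.94693, b = -17.94670),
    r(23, 80, "lang_sokhansanj", a = 2.31625),
    r(23, 80, "rahman", a = 0.27142, beta2 = 1.17238),
    r(23, 80, "correa", a = 0.70713, b = 1.05963),
    r(23, 80, "line", a = 2.51031, b = -1.16293),
    r(23, 80, "exponential", a = 0.72095, b = 1.21226),
    r(23, 100, "bala_woods", a = 0.99175, b = -16.93720),
    r(23, 100, "lang_sokhansanj", a = 2.37193, beta1 = 1.21561),
    r(23, 100, "rahman", a = 0.27138),
    r(23, 100, "correa", a = 0.72227, b = 1.14054),
    r(23, 100, "line", a = 2.41417, b = -1.11077),
    r(23, 100, "exponential", a = 0.74136, b = 1.23357),
    r(23, 120, "bala_woods", a = 1.10554, b = -16.03610),
    r(23, 120, "lang_sokhansanj", a = 3.35812, beta1 = 1.24877),
    r(23, 120, "rahman", a = 0.341239),
    r(23, 120, "correa", a = 0.52231, b = 1.36381),
    r(23, 120, "line", a = 2.14782, b = -1.12214),
    r(23, 120, "exponential", a = 0.81248, b = 1.24151)
  ))
})

#' Reference drying-model parameter sets
#'
#' Published fitted parameters of the eleven thin-layer drying models for
#' soybean dried at 80, 100 and 120 deg C after harvest at 23% or 18%
#' (d.b.) moisture. Useful as realistic generating values in
#' parameter-recovery exercises.
#'
#' @param model optional model name filter.
#' @param air_temp_C optional temperature filter (80, 100, 120).
#' @param harvest_moisture_pct optional harvest-moisture filter (23, 18).
#' @return Long data frame with columns `harvest_moisture_pct`,
#'   `air_temp_C`, `model`, `param`, `value`.
#' @export
reference_drying_params <- function(model = NULL, air_temp_C = NULL,
                                    harvest_moisture_pct = NULL) {
  .filter_ref(.drying_ref, model, air_temp_C, harvest_moisture_pct)
}

#' Reference shrinkage-model parameter sets
#'
#' Published per-condition coefficients of the six unit-volumetric
#' shrinkage models for soybean harvested at 23% (d.b.), carried verbatim
#' (some published rows omit a coefficient; such sets are incomplete and
#' are returned as-is).
#'
#' @inheritParams reference_drying_params
#' @return Long data frame as in [reference_drying_params()].
#' @export
reference_shrinkage_params <- function(model = NULL, air_temp_C = NULL,
                                       harvest_moisture_pct = NULL) {
  .filter_ref(.shrinkage_ref, model, air_temp_C, harvest_moisture_pct)
}

.filter_ref <- function(df, model, air_temp_C, harvest_moisture_pct) {
  if (!is.null(model)) df <- df[df$model %in% model, , drop = FALSE]
  if (!is.null(air_temp_C)) df <- df[df$air_temp_C %in% air_temp_C, , drop = FALSE]
  if (!is.null(harvest_moisture_pct)) {
    df <- df[df$harvest_moisture_pct %in% harvest_moisture_pct, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Extract one reference parameter set as a named vector
#'
#' @param df a reference table from [reference_drying_params()] or
#'   [reference_shrinkage_params()], filtered to a single
#'   model/temperature/harvest combination.
#' @return Named numeric vector of parameters.
#' @export
reference_param_vector <- function(df) {
  if (length(unique(paste(df$model, df$air_temp_C, df$harvest_moisture_pct))) != 1) {
    stop_contract("expected a single model/temperature/harvest combination")
  }
  stats::setNames(df$value, df$param)
}
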