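# Seeded synthetic-data generators. Every generator is a pure function of
# (configuration, seed): the caller's RNG state is saved and restored, so
# the same seed always yields the same data and generation never perturbs
# an enclosing simulation.

#' Generate a synthetic drying curve
#'
#' Evaluates a registered drying model on a regular time grid, inverts the
#' moisture ratio to dry-basis moisture via `X = Xe + MR * (X0 - Xe)`, and
#' adds independent Gaussian measurement noise on the moisture scale
#' (clipped into `(xe, x0]`). The initial observation is left noiseless:
#' the initial moisture is the reference against which the curve is
#' normalized. The default sampling interval of 0.25 h mirrors the
#' 15-minute sampling typical of continuous-dryer experiments.
#'
#' @param spec a drying `model_spec` (see [drying_model()]).
#' @param params generating parameters for `spec`.
#' @param x0 initial dry-basis moisture (decimal).
#' @param xe equilibrium dry-basis moisture (decimal), `xe < x0`.
#' @param duration_h total drying time (h).
#' @param interval_h sampling interval (h), default 0.25.
#' @param noise_sd SD of the additive Gaussian noise on moisture (d.b.
#'   decimal), default 0.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param air_temp_C metadata passed through to the curve.
#' @return A [drying_curve()].
#' @export
gen_drying_curve <- function(spec, params, x0, xe, duration_h,
                             interval_h = 0.25, noise_sd = 0, seed = NULL,
                             air_temp_C = NA_real_) {
  stopifnot(duration_h > 0, interval_h > 0, noise_sd >= 0, xe < x0)
  t <- seq(0, duration_h, by = interval_h)
  mr <- evaluate_model(spec, params, t)
  x <- xe + mr * (x0 - xe)
  if (noise_sd > 0) {
    x <- with_seed(seed, x + c(0, stats::rnorm(length(x) - 1, 0, noise_sd)))
  }
  eps <- 1e-9
  x <- pmin(pmax(x, xe + eps), x0)
  drying_curve(time_h = t, moisture_db = x, x0 = x0, xe = xe,
               air_temp_C = air_temp_C,
               label = sprintf("synthetic %s", spec$name),
               tol = max(0.02, 4 * noise_sd))
}

#' Generate a synthetic shrinkage series
#'
#' Evaluates a registered shrinkage model over a decreasing moisture grid
#' from `x0` to `x_final` and adds Gaussian noise on psi (the first,
#' reference observation stays noiseless).
#'
#' @param spec a shrinkage `model_spec` (see [shrinkage_model()]).
#' @param params generating parameters.
#' @param x0 initial dry-basis moisture (decimal).
#' @param x_final final moisture (< x0).
#' @param n_points number of observations (>= 2).
#' @param noise_sd SD of additive Gaussian noise on psi, default 0.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param validate validate ranges via [shrinkage_series()] (default).
#'   Disable to accept published parameter sets that evaluate outside the
#'   physical (0, 1.2] band, e.g. for parameter-recovery exercises.
#' @return A [shrinkage_series()] (or a bare data frame with an `x0`
#'   attribute when `validate = FALSE`).
#' @export
gen_shrinkage_series <- function(spec, params, x0, x_final, n_points = 12,
                                 noise_sd = 0, seed = NULL, validate = TRUE) {
  stopifnot(x_final < x0, n_points >= 2, noise_sd >= 0)
  x <- seq(x0, x_final, length.out = n_points)
  psi <- evaluate_model(spec, params, x)
  if (noise_sd > 0) {
    psi <- with_seed(seed, psi + c(0, stats::rnorm(n_points - 1, 0, noise_sd)))
  }
  if (validate) {
    shrinkage_series(moisture_db = x, psi = psi, x0 = x0)
  } else {
    out <- data.frame(moisture_db = x, psi = psi)
    attr(out, "x0") <- x0
    out
  }
}

#' Generate a synthetic Fick-sphere moisture-ratio curve
#'
#' Samples the truncated Fick-sphere series on a regular time grid with
#' optional additive Gaussian noise on MR.
#'
#' @inheritParams fick_sphere_mr
#' @param duration_s total time (s).
#' @param interval_s sampling interval (s).
#' @param n_terms series truncation for generation (default 1000: near
#'   t = 0 many terms are needed for MR to reach 1 within the truncation
#'   bound `6 / (pi^2 N)`).
#' @param noise_sd SD of additive Gaussian noise on MR, default 0.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return An [mr_series()] (times converted to hours).
#' @export
gen_fick_curve <- function(d_m2s, radius_m, duration_s, interval_s,
                           n_terms = 1000, noise_sd = 0, seed = NULL) {
  stopifnot(duration_s > 0, interval_s > 0, noise_sd >= 0)
  t_s <- seq(0, duration_s, by = interval_s)
  mr <- fick_sphere_mr(d_m2s, radius_m, t_s, n_terms)
  if (noise_sd > 0) {
    mr <- with_seed(seed, mr + stats::rnorm(length(mr), 0, noise_sd))
    mr <- pmin(pmax(mr, 0), 1.05)
  }
  mr_series(time_h = t_s / 3600, mr = mr)
}

# severity of the storage stress for each (time, storage temp, package)
# cell, in arbitrary damage units. time 0 is pristine everywhere (the
# quality of a lot at the start of storage cannot depend on where it will
# be stored). The 12 stressed cells fall into three well-separated
# severity bands - mild, moderate, severe - each internally ordered so
# that severity grows with time, temperature and package permeability
# (paper bags breathe; polyethylene liners protect). Together with the
# fresh (time 0) cells this plants exactly four groups in the factorial.
.default_severity <- function() {
  d <- expand.grid(time_months = c(0, 4, 8), storage_temp_C = c(15, 23, 30),
                   package = c("P", "PL"), stringsAsFactors = FALSE)
  key <- function(tm, st, pk) d$time_months == tm & d$storage_temp_C == st & d$package == pk
  d$severity <- 0
  d$severity[key(4, 15, "PL")] <- 3.0
  d$severity[key(4, 15, "P")]  <- 3.2
  d$severity[key(4, 23, "PL")] <- 3.4
  d$severity[key(8, 15, "PL")] <- 3.6
  d$severity[key(4, 23, "P")]  <- 7.0
  d$severity[key(4, 30, "PL")] <- 7.2
  d$severity[key(8, 15, "P")]  <- 7.4
  d$severity[key(8, 23, "PL")] <- 7.6
  d$severity[key(4, 30, "P")]  <- 11.0
  d$severity[key(8, 23, "P")]  <- 11.2
  d$severity[key(8, 30, "PL")] <- 11.4
  d$severity[key(8, 30, "P")]  <- 11.6
  d$group <- c("fresh", "mild", "moderate", "severe")[
    findInterval(d$severity, c(-Inf, 1, 5, 9)) ]
  d
}

#' Configuration of the synthetic storage-quality factorial
#'
#' Defines the data-generating process for a storage experiment crossing
#' harvest moisture (18, 23% d.b.) x drying temperature (80, 100, 120 deg C
#' and a mixed lot) x storage temperature (15, 23, 30 deg C) x package
#' (paper `P`, polyethylene `PL`) x storage time (0, 4, 8 months), with
#' replicates.
#'
#' Each quality variable responds linearly to a latent damage score: the
#' sum of a drying/harvest component (higher drying temperature and the
#' wetter handling of an 18% harvest damage the grain before storage
#' begins) and a storage-severity component determined by time,
#' temperature and package. Oil and crude protein decrease with damage
#' while electrical conductivity (membrane leakage) and lipid acidity
#' increase, which is what couples the variables: EC is anti-correlated
#' with oil and protein, and oil and protein move together. The severity
#' component takes values in three separated bands (plus zero at time 0),
#' planting a four-group structure ("fresh", "mild", "moderate",
#' "severe") that Ward clustering of treatment means should recover; the
#' planted group is returned with each record so recovery can be scored.
#'
#' Baselines default to a fresh, gently dried lot (80 deg C, 23% harvest):
#' moisture 10.31% d.b., EC 191 uS cm^-1 g^-1, oil 25.89%, acidity
#' 5.54 mL, protein 35.69%. Response coefficients are per unit damage;
#' with the default severity bands (up to 11.6 at 8 months, 30 deg C,
#' paper bag) the severe cells lose roughly 5% oil and 10 points of
#' protein and gain roughly 160 uS cm^-1 g^-1 of EC relative to fresh,
#' the order of magnitude seen in stored-soybean quality tables.
#'
#' @param baselines named vector of variable baselines.
#' @param coef named vector: response per unit damage for each variable.
#' @param dry_damage named vector: damage contributed by drying at 80,
#'   100, 120 deg C or a mixed lot.
#' @param harvest_damage named vector: extra damage by harvest moisture.
#' @param severity data frame with columns `time_months`,
#'   `storage_temp_C`, `package`, `severity`, `group` covering all 18
#'   cells (defaults to the banded severity table described above).
#' @param noise_sd named vector of measurement-noise SDs per variable.
#' @param n_reps replicates per treatment (default 3).
#' @return An object of class `storage_config`.
#' @export
storage_effect_config <- function(
    baselines = c(moisture_pct = 10.31, ec = 191, oil_pct = 25.89,
                  acidity_ml = 5.54, protein_pct = 35.69),
    coef = c(moisture_pct = -0.05, ec = 14, oil_pct = -0.45,
             acidity_ml = 0.18, protein_pct = -0.9),
    dry_damage = c("80" = 0, "100" = 0.35, "120" = 0.65, "mixed" = 0.45),
    harvest_damage = c("23" = 0, "18" = 0.15),
    severity = .default_severity(),
    noise_sd = c(moisture_pct = 0.08, ec = 3, oil_pct = 0.15,
                 acidity_ml = 0.06, protein_pct = 0.2),
    n_reps = 3) {
  vars <- STORAGE_VARIABLES
  stopifnot(setequal(names(baselines), vars), setequal(names(coef), vars),
            setequal(names(noise_sd), vars), all(noise_sd >= 0), n_reps >= 1,
            all(c("time_months", "storage_temp_C", "package", "severity",
                  "group") %in% names(severity)))
  if (coef[["oil_pct"]] >= 0 || coef[["protein_pct"]] >= 0 ||
      coef[["ec"]] <= 0 || coef[["acidity_ml"]] <= 0) {
    stop_contract("damage coefficients must decrease oil/protein and increase EC/acidity")
  }
  structure(list(baselines = baselines[vars], coef = coef[vars],
                 dry_damage = dry_damage, harvest_damage = harvest_damage,
                 severity = severity, noise_sd = noise_sd[vars],
                 n_reps = as.integer(n_reps)),
            class = "storage_config")
}

#' Generate the synthetic storage-quality factorial
#'
#' Draws the full factorial of storage records described by a
#' [storage_effect_config()]: 2 harvest moistures x 4 drying temperatures
#' x 3 storage temperatures x 2 packages x 3 times x `n_reps` replicates
#' (432 records at the default 3 replicates).
#'
#' @param config a [storage_effect_config()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return Data frame of storage records with the factor columns, a
#'   `replicate` column, the five quality variables, and the
#'   `planted_group` simulation truth used by recovery tests.
#' @export
gen_storage_table <- function(config = storage_effect_config(), seed = NULL) {
  stopifnot(inherits(config, "storage_config"))
  grid <- expand.grid(
    harvest_moisture_pct = as.numeric(names(config$harvest_damage)),
    drying_temp = names(config$dry_damage),
    storage_temp_C = sort(unique(config$severity$storage_temp_C)),
    package = unique(config$severity$package),
    time_months = sort(unique(config$severity$time_months)),
    replicate = seq_len(config$n_reps),
    stringsAsFactors = FALSE)
  sev_key <- paste(config$severity$time_months, config$severity$storage_temp_C,
                   config$severity$package)
  idx <- match(paste(grid$time_months, grid$storage_temp_C, grid$package), sev_key)
  if (any(is.na(idx))) stop_contract("severity table does not cover all cells")
  damage <- config$severity$severity[idx] +
    config$dry_damage[grid$drying_temp] +
    config$harvest_damage[as.character(grid$harvest_moisture_pct)]
  n <- nrow(grid)
  vals <- with_seed(seed, {
    out <- lapply(STORAGE_VARIABLES, function(v) {
      mu <- config$baselines[[v]] + config$coef[[v]] * damage
      if (config$noise_sd[[v]] > 0) mu + stats::rnorm(n, 0, config$noise_sd[[v]]) else mu
    })
    stats::setNames(out, STORAGE_VARIABLES)
  })
  cbind(grid, as.data.frame(vals),
        planted_group = config$severity$group[idx])
}
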