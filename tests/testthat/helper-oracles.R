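# Independent re-implementations used as oracles. Kept deliberately
# element-by-element (spreadsheet style) so they share no code with the
# package's vectorized formulas.

oracle_P <- function(y, yhat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + abs(y[i] - yhat[i]) / y[i]
  (100 / length(y)) * acc
}

oracle_SE <- function(y, yhat, glr) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - yhat[i])^2
  sqrt(acc / glr)
}

oracle_R2 <- function(y, yhat) {
  m <- sum(y) / length(y)
  sse <- 0; sst <- 0
  for (i in seq_along(y)) {
    sse <- sse + (y[i] - yhat[i])^2
    sst <- sst + (y[i] - m)^2
  }
  100 * (1 - sse / sst)
}

# exact probability that a random arrangement of n1 plus and n2 minus
# signs has exactly r runs, by full enumeration (tiny n only)
oracle_runs_exact <- function(n1, n2, r) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  hits <- 0
  for (j in seq_len(ncol(combos))) {
    s <- rep(-1, n); s[combos[, j]] <- 1
    runs <- 1 + sum(s[-1] != s[-n])
    if (runs == r) hits <- hits + 1
  }
  hits / ncol(combos)
}

# draw ranges used by recovery and oracle tests: physically plausible
# parameter regions for grain drying/shrinkage (magnitudes of published
# estimates), where each model is identifiable
drying_param_draws <- list(
  newton = function() c(k = runif(1, 0.3, 2.5)),
  page = function() c(k = runif(1, 0.3, 1.5), n = runif(1, 0.7, 2)),
  page_modified = function() c(k = runif(1, 0.3, 1.5), n = runif(1, 0.7, 2)),
  henderson_pabis = function() c(a = runif(1, 0.8, 1.2), k = runif(1, 0.3, 2.5)),
  logarithmic = function() c(a = runif(1, 0.8, 1.2), k = runif(1, 0.5, 2.5),
                             c = runif(1, -0.2, 0.2)),
  two_exponential_terms = function() c(a = runif(1, 1.2, 2), k = runif(1, 0.5, 2)),
  wang_singh = function() c(a = runif(1, -0.35, -0.2), b = runif(1, 0.01, 0.03)),
  midilli = function() c(a = runif(1, 0.9, 1.1), k = runif(1, 0.3, 1.5),
                         n = runif(1, 0.8, 1.5), b = runif(1, -0.08, -0.01)),
  diffusion_approximation = function() c(a = runif(1, 0.3, 0.7),
                                         k = runif(1, 0.5, 2),
                                         b = runif(1, 1.5, 3)),
  two_terms = function() c(a = runif(1, 0.3, 0.7), k0 = runif(1, 1.5, 3),
                           b = runif(1, 0.3, 0.7), k1 = runif(1, 0.2, 1)),
  henderson_pabis_modified = function() c(a = runif(1, 0.2, 0.5),
                                          k = runif(1, 1.5, 3),
                                          b = runif(1, 0.2, 0.5),
                                          k0 = runif(1, 0.2, 1),
                                          c = runif(1, 0.1, 0.4),
                                          k1 = runif(1, 3, 6))
)

shrinkage_param_draws <- list(
  bala_woods = function() c(a = runif(1, 0.8, 1.1), b = runif(1, -25, -8)),
  lang_sokhansanj = function() c(a = runif(1, 0.3, 1), beta1 = runif(1, 0.5, 2)),
  rahman = function() c(a = runif(1, 0.3, 1), beta2 = runif(1, 0.5, 2)),
  correa = function() c(a = runif(1, 0.4, 0.8), b = runif(1, 0.8, 1.5)),
  line = function() c(a = runif(1, 1.5, 3), b = runif(1, -2, -0.5)),
  exponential = function() c(a = runif(1, 0.5, 0.9), b = runif(1, 0.8, 1.6))
)

# planted group of each treatment row of a treatment_matrix() built from
# gen_storage_table() output
planted_groups_for <- function(records, m) {
  fac <- graindry:::STORAGE_FACTORS
  pg <- stats::aggregate(records["planted_group"], by = records[fac],
                         FUN = function(z) z[1])
  key <- do.call(paste, c(pg[fac], list(sep = "/")))
  pg$planted_group[match(rownames(m), key)]
}
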