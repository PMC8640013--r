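test_that("noiseless drying curves round-trip through the moisture ratio", {
  sp <- drying_model("page")
  p <- c(k = 0.29353, n = 1.61707)
  dc <- gen_drying_curve(sp, p, x0 = 0.23, xe = 0.03, duration_h = 2.5)
  mr <- moisture_ratio(dc)
  expect_equal(mr$mr, evaluate_model(sp, p, mr$time_h), tolerance = 1e-12)
  expect_equal(dc$moisture_db[1], 0.23)
})

test_that("the published Wang & Singh curve yields 11 decreasing samples over 2.6 h", {
  sp <- drying_model("wang_singh")
  p <- reference_param_vector(
    reference_drying_params("wang_singh", 80, 23))
  dc <- gen_drying_curve(sp, p, x0 = 0.23, xe = 0.03, duration_h = 2.6,
                         interval_h = 0.25)
  expect_length(dc$time_h, 11)
  expect_true(all(diff(dc$moisture_db) < 0))
})

test_that("generators are pure functions of (config, seed)", {
  sp <- drying_model("newton")
  a <- gen_drying_curve(sp, c(k = 0.7), 0.23, 0.03, 2.5, noise_sd = 0.005,
                        seed = 99)
  b <- gen_drying_curve(sp, c(k = 0.7), 0.23, 0.03, 2.5, noise_sd = 0.005,
                        seed = 99)
  expect_identical(a$moisture_db, b$moisture_db)
  # the global RNG stream is untouched by seeded generation
  set.seed(1); before <- .Random.seed
  invisible(gen_storage_table(seed = 5))
  expect_identical(.Random.seed, before)
  s1 <- gen_storage_table(seed = 5)
  s2 <- gen_storage_table(seed = 5)
  expect_identical(s1, s2)
})

test_that("shrinkage generation round-trips and respects monotone inputs", {
  sp <- shrinkage_model("line")
  p <- c(a = 2.51031, b = -1.16293)
  # this published pair evaluates psi above 1 near x0; skip validation as
  # a recovery exercise would
  s <- gen_shrinkage_series(sp, p, x0 = 0.23, x_final = 0.11, n_points = 10,
                            validate = FALSE)
  expect_equal(s$psi, evaluate_model(sp, p, s$moisture_db), tolerance = 1e-12)
  expect_true(all(diff(s$psi) > 0 | diff(s$psi) < 0))  # monotone for a line
  # a physical parameter set passes validation
  s2 <- gen_shrinkage_series(shrinkage_model("rahman", x0 = 0.23),
                             c(a = 1, beta2 = 1.2), x0 = 0.23,
                             x_final = 0.11, n_points = 10)
  expect_s3_class(s2, "shrinkage_series")
  expect_equal(s2$psi[1], 1)
})

test_that("fick-curve generation honours the truncation bound at t = 0", {
  mr <- gen_fick_curve(4.9e-10, 0.003, duration_s = 9360, interval_s = 300,
                       n_terms = 1000)
  expect_equal(nrow(mr), 32L)
  expect_lt(abs(mr$mr[1] - 1), 6 / (pi^2 * 1000))
})

test_that("the storage factorial has the designed size and structure", {
  tab <- gen_storage_table(seed = 1)
  expect_identical(nrow(tab), 432L)
  expect_identical(sort(unique(tab$time_months)), c(0, 4, 8))
  expect_identical(sort(unique(tab$drying_temp)),
                   sort(c("80", "100", "120", "mixed")))
  # time 0 is uniformly "fresh" regardless of the storage condition
  expect_true(all(tab$planted_group[tab$time_months == 0] == "fresh"))
  expect_identical(sort(unique(tab$planted_group)),
                   c("fresh", "mild", "moderate", "severe"))
})

test_that("noiseless storage trends follow the planted degradation", {
  cfg <- storage_effect_config(noise_sd = c(moisture_pct = 0, ec = 0,
                                            oil_pct = 0, acidity_ml = 0,
                                            protein_pct = 0))
  tab <- gen_storage_table(cfg, seed = 1)
  # oil always degrades over 8 months, in every cell
  cell <- interaction(tab$harvest_moisture_pct, tab$drying_temp,
                      tab$storage_temp_C, tab$package)
  for (cg in levels(cell)) {
    sub <- tab[cell == cg, ]
    expect_lt(mean(sub$oil_pct[sub$time_months == 8]),
              mean(sub$oil_pct[sub$time_months == 0]))
    expect_gt(mean(sub$ec[sub$time_months == 8]),
              mean(sub$ec[sub$time_months == 0]))
  }
  # worst cell (30 degC, paper) leaches more than the best (15 degC, PL)
  ec8 <- function(st, pk) mean(tab$ec[tab$time_months == 8 &
                                        tab$storage_temp_C == st &
                                        tab$package == pk])
  expect_gt(ec8(30, "P"), ec8(15, "PL"))
})

test_that("config validation rejects wrongly signed trends", {
  expect_error(storage_effect_config(coef = c(moisture_pct = -0.05, ec = -14,
                                              oil_pct = -0.45,
                                              acidity_ml = 0.18,
                                              protein_pct = -0.9)),
               "increase EC")
  expect_error(storage_effect_config(noise_sd = c(moisture_pct = -1, ec = 3,
                                                  oil_pct = 0.15,
                                                  acidity_ml = 0.06,
                                                  protein_pct = 0.2)))
})
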