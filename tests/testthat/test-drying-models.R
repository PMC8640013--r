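test_that("moisture ratio normalizes a drying record", {
  dc <- drying_curve(time_h = c(0, 1, 2), moisture_db = c(0.23, 0.11, 0.06),
                     x0 = 0.23, xe = 0.03)
  mr <- moisture_ratio(dc)
  expect_s3_class(mr, "mr_series")
  expect_equal(mr$mr[1], 1)                      # X = X0
  expect_equal(mr$mr[2], 0.08 / 0.20)            # hand arithmetic: 0.400
  dc2 <- drying_curve(c(0, 1), c(0.23, 0.0300001), x0 = 0.23, xe = 0.03)
  expect_equal(moisture_ratio(dc2)$mr[2], 0, tolerance = 1e-4)  # X = Xe
})

test_that("moisture ratio guards its preconditions", {
  dc <- drying_curve(c(0, 1), c(0.23, 0.11), x0 = 0.23, xe = NULL)
  expect_warning(moisture_ratio(dc), "fallback")
  # x0 <= xe is an invalid configuration
  bad <- drying_curve(c(0, 1), c(0.23, 0.11), x0 = 0.23, xe = 0.05)
  bad$xe <- 0.5
  expect_error(moisture_ratio(bad), "must exceed")
  # values below xe are clipped to 0 with a warning, not negative
  dc3 <- drying_curve(c(0, 1, 2), c(0.23, 0.11, 0.06), x0 = 0.23, xe = 0.05)
  dc3$moisture_db[3] <- 0.04  # dip below xe, as a noisy tail would
  expect_warning(mr <- moisture_ratio(dc3), "clipping")
  expect_identical(mr$mr[3], 0)
})

test_that("drying curve invariants are enforced", {
  expect_error(drying_curve(c(0.5, 1), c(0.2, 0.1), x0 = 0.2), "start at 0")
  expect_error(drying_curve(c(0, 1, 1), c(0.2, 0.15, 0.1), x0 = 0.2),
               "strictly increasing")
  expect_error(drying_curve(c(0, 1), c(0.2, 1.2), x0 = 0.2), "\\(0, 1\\)")
  expect_error(drying_curve(c(0, 1), c(0.2, 0.1), x0 = 0.3), "does not match x0")
  expect_error(drying_curve(c(0, 1), c(0.2, 0.1), x0 = 0.2, xe = 0.15),
               "below all observed")
})

test_that("closed forms match independent evaluation", {
  # Newton at the published 80 degC drying constant
  expect_equal(evaluate_model(drying_model("newton"), c(k = 0.4636), 1),
               exp(-0.4636), tolerance = 1e-12)
  expect_equal(exp(-0.4636), 0.62901, tolerance = 1e-5)
  # Wang & Singh at the published 80 degC pair, end of drying (2.6 h)
  ws <- evaluate_model(drying_model("wang_singh"),
                       c(a = -0.2849, b = 0.002680), 2.6)
  expect_equal(ws, 1 - 0.2849 * 2.6 + 0.002680 * 2.6^2, tolerance = 1e-12)
  expect_equal(ws, 0.27738, tolerance = 1e-4)
  # Midilli combines a stretched exponential and a linear drift
  p <- c(a = 0.99, k = 0.5, n = 1.2, b = -0.05)
  expect_equal(evaluate_model(drying_model("midilli"), p, 2),
               0.99 * exp(-0.5 * 2^1.2) - 0.05 * 2, tolerance = 1e-12)
})

test_that("parameter contracts are enforced", {
  sp <- drying_model("newton")
  expect_error(evaluate_model(sp, c(q = 1), 1), "exactly parameters")
  expect_error(evaluate_model(sp, c(k = 1, n = 1), 1), "exactly parameters")
  expect_error(evaluate_model(sp, c(k = 1), -1), "non-negative")
  expect_error(drying_model("not_a_model"))
})

test_that("every model is normalized to MR = 1 at t = 0 under its own normalization", {
  norm_params <- list(
    newton = c(k = 0.7), page = c(k = 0.7, n = 1.3),
    page_modified = c(k = 0.7, n = 1.3),
    henderson_pabis = c(a = 1, k = 0.7),
    logarithmic = c(a = 0.9, k = 0.7, c = 0.1),
    two_terms = c(a = 0.4, k0 = 0.9, b = 0.6, k1 = 0.3),
    two_exponential_terms = c(a = 1.6, k = 0.8),
    wang_singh = c(a = -0.3, b = 0.02),
    henderson_pabis_modified = c(a = 0.2, k = 0.9, b = 0.3, k0 = 0.5,
                                 c = 0.5, k1 = 1.4),
    midilli = c(a = 1, k = 0.7, n = 1.2, b = -0.05),
    diffusion_approximation = c(a = 0.6, k = 0.8, b = 2))
  for (m in drying_models()) {
    expect_equal(evaluate_model(drying_model(m), norm_params[[m]], 0), 1,
                 tolerance = 1e-12, label = m)
  }
})

test_that("special cases reduce to the Newton model", {
  t <- seq(0, 3, 0.1)
  k <- 0.83
  newton <- evaluate_model(drying_model("newton"), c(k = k), t)
  expect_equal(evaluate_model(drying_model("page"), c(k = k, n = 1), t),
               newton, tolerance = 1e-12)
  expect_equal(evaluate_model(drying_model("two_exponential_terms"),
                              c(a = 1, k = k), t), newton, tolerance = 1e-12)
  expect_equal(evaluate_model(drying_model("diffusion_approximation"),
                              c(a = 1, k = k, b = 7), t), newton,
               tolerance = 1e-12)
})

test_that("exponential-decay models decrease monotonically for positive rates", {
  t <- seq(0, 3, 0.05)
  set.seed(11)
  for (i in 1:10) {
    k <- runif(1, 0.1, 3)
    a <- runif(1, 0.5, 1.5)
    expect_true(all(diff(evaluate_model(drying_model("newton"), c(k = k), t)) < 0))
    expect_true(all(diff(evaluate_model(drying_model("page"),
                                        c(k = k, n = runif(1, 0.5, 2)), t)) < 0))
    expect_true(all(diff(evaluate_model(drying_model("henderson_pabis"),
                                        c(a = a, k = k), t)) < 0))
  }
})
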