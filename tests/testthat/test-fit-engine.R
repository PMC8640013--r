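test_that("goodness-of-fit statistics match hand arithmetic", {
  y <- c(1, 0.5, 0.25); yhat <- c(0.9, 0.5, 0.3)
  expect_equal(r_squared(y, y), 100)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, yhat), 100 * (1 - 0.0125 / (0.175 / 0.6)),
               tolerance = 1e-10)
  expect_equal(r_squared(y, yhat), 95.714, tolerance = 1e-4)

  expect_equal(mean_relative_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_relative_error(c(1, 2), c(1.1, 1.8)), 10)
  # P is linear in the residual magnitudes
  expect_equal(mean_relative_error(c(1, 2), c(1.2, 1.6)), 20)

  expect_equal(standard_error(c(1, 2), c(1, 2), 1), 0)
  expect_equal(standard_error(c(1, 2), c(0.9, 2.1), 2), 0.1, tolerance = 1e-12)
  expect_equal(standard_error(1, 0.7, 1), 0.3, tolerance = 1e-12)

  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
  expect_error(mean_relative_error(c(0, 1), c(1, 1)), "undefined")
  expect_error(standard_error(c(1, 2), c(1, 2), 0), "at least 1")
})

test_that("P, SE and R2 agree with independent re-implementations", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    y <- runif(n, 0.2, 2)
    yhat <- y + rnorm(n, 0, 0.1)
    expect_equal(mean_relative_error(y, yhat), oracle_P(y, yhat),
                 tolerance = 1e-12)
    expect_equal(standard_error(y, yhat, n - 2), oracle_SE(y, yhat, n - 2),
                 tolerance = 1e-12)
    expect_equal(r_squared(y, yhat), oracle_R2(y, yhat), tolerance = 1e-12)
  }
})

test_that("residual classification separates trends from sign-balanced noise", {
  # alternating signs: the maximum number of runs, no trend
  expect_identical(as.character(classify_residuals(rep(c(0.1, -0.1), 4))),
                   "random")
  # monotone drift: a single sign change only
  expect_identical(as.character(classify_residuals(c(rep(0.1, 4), rep(-0.1, 4)))),
                   "tendentious")
  # all residuals the same sign: one run
  expect_identical(as.character(classify_residuals(rep(0.2, 6))), "tendentious")
  # a perfect fit carries no information and is random by convention
  expect_identical(as.character(classify_residuals(rep(0, 8))), "random")
  # zeros inherit the previous sign
  cl <- classify_residuals(c(0.1, 0, -0.1, 0.1, -0.1, 0.1))
  expect_identical(as.character(cl), "random")
  expect_error(classify_residuals(c(1, -1)), "at least 5")
})

test_that("the exact runs-test tail matches full enumeration", {
  # P(R <= r) for n1 = n2 = 4 against brute-force enumeration of all
  # C(8,4) arrangements
  for (r in 2:8) {
    enum <- sum(vapply(2:r, function(rr) oracle_runs_exact(4, 4, rr), numeric(1)))
    expect_equal(graindry:::runs_p_lower(r, 4, 4), enum, tolerance = 1e-12)
  }
  # the monotone pattern is in the 5% tail, the alternating one is not
  expect_lt(graindry:::runs_p_lower(2, 4, 4), 0.05)
  expect_equal(graindry:::runs_p_lower(8, 4, 4), 1, tolerance = 1e-12)
})

test_that("fit_model recovers a published Newton constant from its own curve", {
  t <- seq(0, 2.5, by = 0.25)
  sp <- drying_model("newton")
  y <- evaluate_model(sp, c(k = 0.4636), t)
  f <- fit_model(t, y, sp, seed = 1)
  expect_equal(unname(f$params["k"]), 0.4636, tolerance = 1e-5)
  expect_gt(f$r2_pct, 99.999)
  expect_identical(f$residual_class, "random")
  expect_true(f$converged)
})

test_that("a non-decaying response drives the Newton rate to its lower bound", {
  t <- seq(0, 2.5, by = 0.25)
  f <- fit_model(t, rep(1, length(t)) + 1e-9 * t, drying_model("newton"), seed = 1)
  expect_equal(unname(f$params["k"]), 1e-6, tolerance = 1e-3)
  expect_true(f$at_bounds)
})

test_that("the wrong model cannot beat the generating model's SSE", {
  t <- seq(0, 2.25, by = 0.25)  # 10 points
  page <- drying_model("page")
  y <- evaluate_model(page, c(k = 0.29353, n = 1.61707), t)
  f_newton <- fit_model(t, y, drying_model("newton"), seed = 1)
  f_page <- fit_model(t, y, page, seed = 1)
  # grid oracle confirms the Newton optimum
  g <- brute_force_fit(t, y, drying_model("newton"),
                       lower = c(k = 0.05), upper = c(k = 2), step = 1e-4)
  expect_lte(f_newton$sse, attr(g, "sse") + 1e-10)
  expect_gt(f_newton$sse, f_page$sse)
  expect_lt(f_page$sse, 1e-12)
})

test_that("fit_model is deterministic given a seed and contract-checks its input", {
  t <- seq(0, 2.5, by = 0.25)
  y <- evaluate_model(drying_model("page"), c(k = 0.5, n = 1.3), t)
  f1 <- fit_model(t, y, drying_model("page"), seed = 7)
  f2 <- fit_model(t, y, drying_model("page"), seed = 7)
  expect_identical(f1$params, f2$params)
  expect_error(fit_model(t[1:3], y[1:3], drying_model("midilli")), "at least")
  expect_error(fit_model(rep(1, 5), y[1:5], drying_model("newton")),
               "degenerate")
})

test_that("noiseless self-generated drying data recover identifiable parameters", {
  t <- seq(0, 2.75, by = 0.25)  # 12 points
  identifiable <- setdiff(drying_models(),
                          c("two_terms", "henderson_pabis_modified"))
  set.seed(42)
  for (m in identifiable) {
    sp <- drying_model(m)
    ok <- 0
    for (i in 1:50) {
      p <- drying_param_draws[[m]]()
      y <- evaluate_model(sp, p, t)
      f <- fit_model(t, y, sp, n_starts = 8, seed = 1000 + i)
      rel <- max(abs(f$params[names(p)] - p) / pmax(abs(p), 1e-8))
      if (rel <= 1e-3) ok <- ok + 1
    }
    expect_gte(ok, 48)  # >= 95% of 50 draws
  }
})

test_that("exponential-sum models are recovered in function space", {
  # two_terms and henderson_pabis_modified are identified only up to
  # permutation and near-degeneracy of their components; the fitted curve,
  # not the parameter vector, is the meaningful target
  t <- seq(0, 2.75, by = 0.25)
  set.seed(42)
  for (m in c("two_terms", "henderson_pabis_modified")) {
    sp <- drying_model(m)
    for (i in 1:20) {
      p <- drying_param_draws[[m]]()
      y <- evaluate_model(sp, p, t)
      f <- fit_model(t, y, sp, n_starts = 8, seed = 3000 + i)
      expect_lt(max(abs(f$fitted - y)), 1e-4)
    }
  }
})

test_that("recovered Newton rate is unbiased under Gaussian noise", {
  t <- seq(0, 5, length.out = 21)
  sp <- drying_model("newton")
  k_true <- 0.7
  mu <- evaluate_model(sp, c(k = k_true), t)
  set.seed(12)
  ks <- replicate(200, {
    y <- mu + rnorm(21, 0, 0.01)
    unname(fit_model(t, y, sp, n_starts = 4, seed = 1)$params["k"])
  })
  mcse <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - k_true), 2 * mcse + 1e-4)
})

test_that("model ranking applies its lexicographic rules", {
  t <- seq(0, 2.5, by = 0.25)
  y <- evaluate_model(drying_model("wang_singh"), c(a = -0.28, b = 0.015), t)
  fits <- lapply(drying_models(), function(m)
    fit_model(t, y, drying_model(m), seed = 2))
  rk <- rank_models(fits)
  expect_identical(rk$model[1], "wang_singh")  # zero SSE beats everything
  expect_identical(rk$rank, seq_len(nrow(rk)))
  # single result ranks first trivially
  expect_identical(rank_models(fits[1])$rank, 1L)
  # residual class dominates, then P, then SE, then R2
  mk <- function(model, se, p, cls, r2 = 99) {
    structure(list(model_name = model, params = c(k = 1), r2_pct = r2,
                   se = se, p_pct = p, residual_class = cls, n_obs = 10,
                   glr = 9, sse = se^2 * 9, converged = TRUE,
                   at_bounds = FALSE, fitted = 1:10, residuals = rep(0, 10),
                   param_se = NULL, param_p = NULL), class = "fit_result")
  }
  rk2 <- rank_models(list(mk("worse_se", 0.2, 5, "random"),
                          mk("better_se", 0.1, 5, "random"),
                          mk("tendentious", 0.01, 1, "tendentious"),
                          mk("high_p", 0.05, 30, "random")))
  expect_identical(rk2$model,
                   c("better_se", "worse_se", "high_p", "tendentious"))
  expect_identical(rk2$verdict,
                   c("acceptable", "acceptable", "not acceptable",
                     "not acceptable"))
})

test_that("brute_force_fit enforces its contract", {
  t <- seq(0, 2, 0.25)
  y <- evaluate_model(drying_model("newton"), c(k = 0.5), t)
  g <- brute_force_fit(t, y, drying_model("newton"),
                       lower = c(k = 0.1), upper = c(k = 1), step = 1e-3)
  expect_equal(unname(g["k"]), 0.5, tolerance = 1e-3)
  expect_error(brute_force_fit(t, y, drying_model("midilli")), "at most 2")
  expect_error(brute_force_fit(t, y, drying_model("newton"),
                               lower = c(k = 1), upper = c(k = 1)),
               "degenerate")
})
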