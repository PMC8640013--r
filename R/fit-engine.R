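# Nonlinear least-squares fitting of registered models plus the
# goodness-of-fit statistics customary in the thin-layer drying
# literature: R^2 (percent), mean relative error P, average estimated
# error SE, and a runs-test classification of the residual distribution.

#' Coefficient of determination (percent)
#'
#' `100 * (1 - SSE / SStot)` with the total sum of squares taken about
#' the mean of the observations.
#'
#' @param y observed values (non-constant, length >= 2).
#' @param yhat fitted values, same length.
#' @return R^2 in percent (can be negative for fits worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  check_numeric(y, "y"); check_numeric(yhat, "yhat")
  if (length(y) != length(yhat)) stop_contract("`y` and `yhat` lengths differ")
  if (length(y) < 2) stop_contract("need at least 2 observations")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop_contract("`y` is constant; R^2 is undefined")
  100 * (1 - sum((y - yhat)^2) / sstot)
}

#' Mean relative error P (percent)
#'
#' `P = (100 / n) * sum(|Y - Yhat| / Y)`. Divides by the observed value,
#' so it is not symmetric in its arguments and requires all observations
#' to be nonzero. In the drying literature P below about 10% is commonly
#' taken as an adequate fit.
#'
#' @inheritParams r_squared
#' @return P in percent.
#' @export
mean_relative_error <- function(y, yhat) {
  check_numeric(y, "y"); check_numeric(yhat, "yhat")
  if (length(y) != length(yhat)) stop_contract("`y` and `yhat` lengths differ")
  if (any(y == 0)) stop_contract("P is undefined when any observed value is 0")
  100 / length(y) * sum(abs(y - yhat) / abs(y))
}

#' Average estimated error SE
#'
#' `SE = sqrt(sum((Y - Yhat)^2) / GLR)` where GLR is the residual degrees
#' of freedom of the model (observations minus fitted parameters).
#' Reported in the units of the response.
#'
#' @inheritParams r_squared
#' @param glr residual degrees of freedom, at least 1.
#' @return SE in response units.
#' @export
standard_error <- function(y, yhat, glr) {
  check_numeric(y, "y"); check_numeric(yhat, "yhat")
  if (length(y) != length(yhat)) stop_contract("`y` and `yhat` lengths differ")
  stopifnot(is.numeric(glr), length(glr) == 1)
  if (glr < 1) stop_contract("`glr` must be at least 1")
  sqrt(sum((y - yhat)^2) / glr)
}

# Exact lower-tail p-value of the Wald-Wolfowitz runs statistic:
# P(R <= r) given n1 positive and n2 negative signs. Exact combinatorial
# distribution for moderate n, normal approximation beyond.
runs_p_lower <- function(r, n1, n2) {
  n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(if (r <= 1) 1 else 1)
  if (n <= 60) {
    pr <- function(rr) {
      if (rr %% 2 == 0) {
        k <- rr / 2
        2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / choose(n, n1)
      } else {
        k <- (rr - 1) / 2
        (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
           choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / choose(n, n1)
      }
    }
    sum(vapply(2:max(2, r), pr, numeric(1)))
  } else {
    mu <- 2 * n1 * n2 / n + 1
    s2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    if (s2 <= 0) return(1)
    stats::pnorm((r - mu + 0.5) / sqrt(s2))
  }
}

#' Classify a residual distribution as random or tendentious
#'
#' Applies a Wald-Wolfowitz runs test to the signs of the residuals.
#' Residuals equal to zero inherit the preceding sign (an all-zero
#' residual vector - a perfect fit - is classified random by convention).
#' A systematic, trending residual pattern produces few sign runs, so the
#' test is one-sided on the lower tail of the run-count distribution:
#' the fit is `"tendentious"` when the exact probability of observing as
#' few or fewer runs falls below `alpha`, and `"random"` otherwise.
#' (Long alternating patterns - many runs - indicate negative serial
#' correlation, not a systematic lack of fit, and are left as random.)
#'
#' @param residuals numeric vector of at least 5 residuals.
#' @param alpha significance level (default 0.05).
#' @return `"random"` or `"tendentious"`, with the lower-tail p-value and
#'   run count attached as attributes `p_value` and `runs`.
#' @export
classify_residuals <- function(residuals, alpha = 0.05) {
  check_numeric(residuals, "residuals")
  if (length(residuals) < 5) stop_contract("need at least 5 residuals")
  stopifnot(alpha > 0, alpha < 1)
  s <- sign(residuals)
  # zeros take the previous sign; leading zeros take the first nonzero sign
  nz <- which(s != 0)
  if (length(nz) == 0) {
    return(structure("random", p_value = 1, runs = 1L))
  }
  s[seq_len(nz[1] - 1)] <- s[nz[1]]
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  r <- 1L + sum(s[-1] != s[-length(s)])
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  p <- runs_p_lower(r, n1, n2)
  cls <- if (n1 == 0 || n2 == 0 || p < alpha) "tendentious" else "random"
  structure(cls, p_value = p, runs = r)
}

#' Fit a registered model by bounded multi-start nonlinear least squares
#'
#' Minimizes the sum of squared residuals of a drying or shrinkage model
#' over box-bounded parameters using Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]) from several perturbed starting points; the
#' start with the lowest SSE wins. With a fixed `seed` the fit is fully
#' deterministic.
#'
#' @param x predictor values (time in hours for drying models, dry-basis
#'   moisture for shrinkage models).
#' @param y response values (moisture ratio or psi_g), same length, with
#'   `length(y) >= n_params + 1`.
#' @param spec a `model_spec` from [drying_model()] or [shrinkage_model()].
#' @param init optional named vector of starting values; defaults to the
#'   model's data-driven initialization rule.
#' @param n_starts number of starts: the base initialization plus
#'   `n_starts - 1` copies with multiplicative jitter `U(0.5, 2)` per
#'   parameter.
#' @param seed integer seed for the jitter (restores the caller's RNG
#'   state afterwards); `NULL` uses the current RNG stream.
#' @param alpha significance level passed to [classify_residuals()].
#' @return An object of class `fit_result`: list with `model_name`,
#'   `params`, `r2_pct`, `se`, `p_pct` (NA when some `y` is 0),
#'   `residual_class`, `n_obs`, `glr`, `sse`, `converged`, `at_bounds`,
#'   `fitted`, `residuals`, and the coefficient standard errors and
#'   t-test p-values (`param_se`, `param_p`) from the Jacobian-based
#'   covariance where available.
#' @export
fit_model <- function(x, y, spec, init = NULL, n_starts = 8, seed = NULL,
                      alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  check_numeric(x, "x"); check_numeric(y, "y")
  if (length(x) != length(y)) stop_contract("`x` and `y` lengths differ")
  npar <- length(spec$params)
  if (length(y) < npar + 1) {
    stop_contract("need at least ", npar + 1, " observations to fit '",
                  spec$name, "'")
  }
  if (stats::var(x) == 0) stop_contract("degenerate predictor: all x equal")
  stopifnot(n_starts >= 1)

  base <- if (is.null(init)) spec$init(x, y) else as_param_vector(init)
  if (!setequal(names(base), spec$params)) {
    stop_contract("init must name exactly {", paste(spec$params, collapse = ", "), "}")
  }
  base <- pmin(pmax(base[spec$params], spec$lower), spec$upper)

  starts <- with_seed(seed, {
    out <- list(base)
    for (i in seq_len(n_starts - 1)) {
      jit <- base * stats::runif(npar, 0.5, 2)
      jit[base == 0] <- stats::runif(sum(base == 0), -0.1, 0.1)
      out[[i + 1]] <- pmin(pmax(jit, spec$lower), spec$upper)
    }
    out
  })

  resid_fn <- function(p) {
    names(p) <- spec$params
    r <- y - spec$fn(as.list(p), x)
    r[!is.finite(r)] <- 1e6
    r
  }

  best <- NULL
  any_converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = spec$lower, upper = spec$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    any_converged <- any_converged || conv
    if (is.null(best) || sse < best$sse - 1e-15) {
      best <- list(fit = fit, sse = sse, converged = conv)
    }
  }
  if (is.null(best)) {
    # every start failed outright; report a non-converged shell at the base
    return(structure(list(
      model_name = spec$name, params = base, r2_pct = NA_real_, se = NA_real_,
      p_pct = NA_real_, residual_class = NA_character_, n_obs = length(y),
      glr = length(y) - npar, sse = NA_real_, converged = FALSE,
      at_bounds = FALSE, fitted = rep(NA_real_, length(y)),
      residuals = rep(NA_real_, length(y)),
      param_se = NULL, param_p = NULL), class = "fit_result"))
  }

  p <- stats::setNames(pmin(pmax(best$fit$par, spec$lower), spec$upper),
                       spec$params)
  fitted <- spec$fn(as.list(p), x)
  res <- y - fitted
  glr <- max(length(y) - npar, 1L)
  at_bounds <- any(abs(p - spec$lower) < 1e-10 | abs(p - spec$upper) < 1e-10)

  # coefficient t-tests from the Jacobian-based covariance (reported only;
  # they play no role in the ranking)
  param_se <- param_p <- NULL
  if (length(y) > npar) {
    covm <- tryCatch({
      ih <- chol2inv(chol(best$fit$hessian))
      ih * best$sse / (length(y) - npar)
    }, error = function(e) NULL)
    if (!is.null(covm) && all(is.finite(diag(covm))) && all(diag(covm) >= 0)) {
      param_se <- stats::setNames(sqrt(diag(covm)), spec$params)
      tval <- p / param_se
      param_p <- 2 * stats::pt(abs(tval), df = length(y) - npar, lower.tail = FALSE)
    }
  }

  structure(list(
    model_name = spec$name,
    params = p,
    r2_pct = if (stats::var(y) > 0) r_squared(y, fitted) else NA_real_,
    se = standard_error(y, fitted, glr),
    p_pct = if (all(y != 0)) mean_relative_error(y, fitted) else NA_real_,
    residual_class = if (length(res) >= 5)
      as.character(classify_residuals(res, alpha)) else NA_character_,
    n_obs = length(y), glr = glr, sse = best$sse,
    converged = best$converged, at_bounds = at_bounds,
    fitted = as.numeric(fitted), residuals = as.numeric(res),
    param_se = param_se, param_p = param_p), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: SSE %.4g, R2 %.2f%%, SE %.4g, P %s, residuals %s%s\n",
              x$model_name, x$sse, x$r2_pct, x$se,
              if (is.na(x$p_pct)) "NA" else sprintf("%.2f%%", x$p_pct),
              x$residual_class,
              if (isTRUE(x$at_bounds)) " [at bounds]" else ""))
  print(signif(x$params, 6))
  invisible(x)
}

#' Rank competing model fits
#'
#' Orders fits of different models to the same data lexicographically:
#' (1) random residual distribution before tendentious, (2) mean relative
#' error P below the acceptability threshold before above, (3) lower
#' average estimated error SE, (4) higher R^2. A fit is judged
#' `"acceptable"` when its residuals are random and P is below the
#' threshold.
#'
#' @param results list of `fit_result` objects fitted to the same data.
#' @param p_threshold acceptability threshold for P (percent, default 10).
#' @return A data frame with one row per model (ordered by rank):
#'   `rank`, `model`, `r2_pct`, `se`, `p_pct`, `residual_class`,
#'   `converged`, `verdict`.
#' @export
rank_models <- function(results, p_threshold = 10) {
  if (length(results) == 0) stop_contract("`results` must be non-empty")
  stopifnot(all(vapply(results, inherits, logical(1), "fit_result")))
  n_obs <- vapply(results, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1) {
    stop_contract("all results must come from the same data (n_obs differ)")
  }
  df <- data.frame(
    model = vapply(results, `[[`, character(1), "model_name"),
    r2_pct = vapply(results, `[[`, numeric(1), "r2_pct"),
    se = vapply(results, `[[`, numeric(1), "se"),
    p_pct = vapply(results, `[[`, numeric(1), "p_pct"),
    residual_class = vapply(results, `[[`, character(1), "residual_class"),
    converged = vapply(results, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  random_first <- ifelse(!is.na(df$residual_class) & df$residual_class == "random", 0, 1)
  p_ok <- ifelse(!is.na(df$p_pct) & df$p_pct < p_threshold, 0, 1)
  ord <- order(random_first, p_ok, df$se, -df$r2_pct)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$verdict <- ifelse(random_first[ord] == 0 & p_ok[ord] == 0,
                       "acceptable", "not acceptable")
  rownames(df) <- NULL
  df[, c("rank", "model", "r2_pct", "se", "p_pct", "residual_class",
         "converged", "verdict")]
}

#' Exhaustive grid minimization of SSE (test oracle)
#'
#' Brute-force least squares over a regular parameter grid, for models
#' with at most two parameters. Intended as an independent optimization
#' oracle in tests, not for routine fitting.
#'
#' @inheritParams fit_model
#' @param lower,upper named bounds of the search box (default: the spec's
#'   own bounds; supply narrower boxes to keep the grid tractable).
#' @param step grid step, either a single value or a named per-parameter
#'   vector.
#' @return Named vector of the grid point with minimal SSE, with the SSE
#'   attached as attribute `sse`.
#' @export
brute_force_fit <- function(x, y, spec, lower = spec$lower,
                            upper = spec$upper, step = 1e-3) {
  stopifnot(inherits(spec, "model_spec"))
  npar <- length(spec$params)
  if (npar > 2) stop_contract("brute_force_fit supports at most 2 parameters")
  lower <- as_param_vector(lower)[spec$params]
  upper <- as_param_vector(upper)[spec$params]
  if (length(step) == 1) step <- stats::setNames(rep(step, npar), spec$params)
  step <- as_param_vector(step)[spec$params]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower)) {
    stop_contract("degenerate grid bounds")
  }
  grids <- lapply(spec$params, function(nm) seq(lower[nm], upper[nm], by = step[nm]))
  if (any(lengths(grids) == 0)) stop_contract("empty parameter grid")

  if (npar == 1) {
    g <- grids[[1]]
    sse <- numeric(length(g))
    for (i in seq_along(x)) {
      v <- spec$fn(stats::setNames(list(g), spec$params), x[i]) - y[i]
      sse <- sse + v^2
    }
  } else {
    g1 <- grids[[1]]; g2 <- grids[[2]]
    A <- matrix(g1, length(g1), length(g2))
    B <- matrix(g2, length(g1), length(g2), byrow = TRUE)
    sse <- 0
    for (i in seq_along(x)) {
      v <- spec$fn(stats::setNames(list(A, B), spec$params), x[i]) - y[i]
      sse <- sse + v^2
    }
  }
  sse[!is.finite(sse)] <- Inf
  k <- which.min(sse)
  best <- if (npar == 1) stats::setNames(grids[[1]][k], spec$params) else {
    i <- (k - 1) %% length(grids[[1]]) + 1
    j <- (k - 1) %/% length(grids[[1]]) + 1
    stats::setNames(c(grids[[1]][i], grids[[2]][j]), spec$params)
  }
  attr(best, "sse") <- sse[k]
  best
}
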