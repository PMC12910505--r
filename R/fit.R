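# Per-stage least-squares estimation and goodness-of-fit metrics.
#
# Each of the five model functions is fitted individually and sequentially
# (pollen beta, viability surface, germination surface, seed link, mass
# link), mirroring the cascade structure: joint optimization would change
# how errors propagate between stages. Observations are pooled to
# treatment means before fitting; nonlinear fits use deterministic
# multi-start to avoid local minima.

#' Goodness-of-fit metrics
#'
#' `rmse()` is the root-mean-square error of aligned observation and
#' prediction vectors, in the units of the observations. `r_squared()` is
#' `1 - SS_res / SS_tot` about the observed mean; it can be negative for
#' predictions worse than the mean. `aggregate_rmse()` averages
#' per-function RMSE values into the single published summary score; the
#' five functions are measured in different units, so the aggregate is a
#' unit-incoherent convention and raises a warning by default — always
#' report the per-function values alongside it.
#'
#' @param obs,pred Aligned numeric vectors.
#' @param per_function Numeric vector of per-function RMSE values.
#' @param warn Warn about mixed units when aggregating (default TRUE).
#' @return A single numeric value.
#' @export
rmse <- function(obs, pred) {
  stop_if(length(obs) != length(pred), "obs and pred must have equal length")
  stop_if(length(obs) == 0, "empty vectors")
  sqrt(mean((obs - pred)^2))
}

#' @rdname rmse
#' @export
aggregate_rmse <- function(per_function, warn = TRUE) {
  stop_if(length(per_function) == 0, "no per-function values")
  stop_if(any(per_function < 0), "RMSE values must be non-negative")
  if (warn) {
    warning("aggregate RMSE averages functions measured in different units; ",
            "report the per-function values alongside it", call. = FALSE)
  }
  mean(per_function)
}

#' @rdname rmse
#' @export
r_squared <- function(obs, pred) {
  stop_if(length(obs) != length(pred), "obs and pred must have equal length")
  stop_if(length(obs) < 2, "need at least two observations")
  ss_tot <- sum((obs - mean(obs))^2)
  stop_if(ss_tot == 0, "zero total variance: R-squared undefined")
  1 - sum((obs - pred)^2) / ss_tot
}

# Container for one fitted stage.
stage_fit <- function(stage, estimates, fixed, residuals, convergence) {
  r2 <- if (nrow(residuals) >= 2 && var(residuals$observed) > 0) {
    r_squared(residuals$observed, residuals$fitted)
  } else NA_real_
  structure(list(stage = stage,
                 estimates = estimates,
                 fixed = fixed,
                 residuals = residuals,
                 rmse = rmse(residuals$observed, residuals$fitted),
                 r_squared = r2,
                 convergence = convergence,
                 n_obs = nrow(residuals)),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("Stage fit: %s (%d treatment means)\n", x$stage, x$n_obs))
  cat("  estimates:", paste(sprintf("%s = %.6g", names(x$estimates),
                                    x$estimates), collapse = ", "), "\n")
  cat(sprintf("  RMSE = %.4g, R^2 = %s\n", x$rmse,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Ordinary least-squares fit of a linear link
#'
#' Fits `y = slope * x + intercept` by OLS. With constant `y` the
#' documented convention is slope 0, intercept `mean(y)`, and R-squared 0.
#'
#' @param x Predictor values (at least 3, non-zero variance).
#' @param y Response values.
#' @param stage Label recorded in the result.
#' @return A `stage_fit` object with estimates `slope` and `intercept`.
#' @export
fit_linear_link <- function(x, y, stage = "linear_link") {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stop_if(length(x) < 3, "need at least 3 points to fit a linear link")
  stop_if(var(x) == 0, "zero predictor variance: link unidentifiable")
  if (var(y) == 0) {
    est <- c(slope = 0, intercept = mean(y))
    fitted <- rep(mean(y), length(y))
    res <- data.frame(x = x, observed = y, fitted = fitted,
                      residual = y - fitted)
    out <- stage_fit(stage, est, fixed = list(), residuals = res,
                     convergence = list(method = "ols", converged = TRUE))
    out$r_squared <- 0  # constant response: explained variance is nil
    return(out)
  }
  fit <- lm(y ~ x)
  est <- c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  res <- data.frame(x = x, observed = y, fitted = unname(fitted(fit)),
                    residual = unname(residuals(fit)))
  stage_fit(stage, est, fixed = list(), residuals = res,
            convergence = list(method = "ols", converged = TRUE))
}

#' Fit the pollen-number beta function
#'
#' Estimates the magnitude parameter `mu` — the single free parameter of
#' the constrained beta function — by least squares against treatment-mean
#' pollen numbers. Haemocytometer counts are first converted to pollen per
#' flower, then averaged per temperature (pollen number does not depend on
#' duration, so durations are pooled). The cardinal temperatures and `t_0`
#' are held fixed; the peak value `n_star` is taken as the observed mean
#' at the optimal temperature unless overridden. The shape exponents are
#' re-derived from the peak constraint at every candidate `mu`.
#'
#' A coarse deterministic grid over `mu_range` locates the basin, then a
#' golden-section search refines the minimizer.
#'
#' @param obs Observation table containing `pollen_count` rows.
#' @param fixed Named list with `t_b`, `t_c`, `t_opt`, `t_0`.
#' @param n_star Optional peak pollen number; default: observed mean at
#'   `t_opt` (an error if absent and no control observations exist).
#' @param conversion A [conversion_params()] object for the count-to-number
#'   conversion.
#' @param mu_range Search interval for `mu`.
#' @return A `stage_fit` with estimate `mu` (plus derived `alpha`, `beta`,
#'   and the `n_star` used, reported in `fixed`).
#' @export
fit_pollen_beta <- function(obs, fixed = list(t_b = 13, t_c = 48, t_opt = 18, t_0 = 1),
                            n_star = NULL, conversion = conversion_params(),
                            mu_range = c(0, 15)) {
  validate_observations(obs)
  rows <- obs[obs$stage == "pollen_count", , drop = FALSE]
  stop_if(nrow(rows) == 0, "no pollen_count observations")
  rows$value <- pollen_count_to_number(rows$value, conversion)
  means <- aggregate(rows["value"], by = list(temperature_C = rows$temperature_C),
                     FUN = mean)
  stop_if(nrow(means) < 3,
          "need observations at >= 3 distinct temperatures to fit the beta function")
  if (is.null(n_star)) {
    at_opt <- means$value[means$temperature_C == fixed$t_opt]
    stop_if(length(at_opt) == 0,
            "n_star unset and no observations at the optimal temperature")
    n_star <- at_opt
  }
  make_params <- function(mu) {
    pollen_beta_params(mu = mu, n_star = n_star, t_b = fixed$t_b,
                       t_c = fixed$t_c, t_opt = fixed$t_opt, t_0 = fixed$t_0)
  }
  sse <- function(mu) {
    pred <- pollen_number(means$temperature_C, make_params(mu))
    sum((means$value - pred)^2)
  }
  # deterministic coarse grid, then local refinement around the best cell
  grid <- seq(mu_range[1], mu_range[2], length.out = 61)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(sse, interval = c(lo, hi), tol = 1e-10)
  mu_hat <- opt$minimum
  p_hat <- make_params(mu_hat)
  sh <- derive_beta_shape(p_hat)
  res <- data.frame(temperature_C = means$temperature_C,
                    observed = means$value,
                    fitted = pollen_number(means$temperature_C, p_hat))
  res$residual <- res$observed - res$fitted
  stage_fit("pollen_number",
            c(mu = mu_hat, alpha = unname(sh["alpha"]), beta = unname(sh["beta"])),
            fixed = c(fixed, list(n_star = n_star)),
            residuals = res,
            convergence = list(method = "grid+golden-section",
                               objective = opt$objective, converged = TRUE))
}

#' Fit a fraction response surface
#'
#' Estimates the duration-interpolation parameters `(theta1, theta2)` of
#' one fraction surface (viability or germination) by least squares
#' against treatment-mean fractions, with `alpha_max` held fixed at the
#' control-treatment measurement (the fraction observed at the optimal
#' temperature). Residuals are computed on the clamped surface, matching
#' its definition. Optimization is Nelder-Mead from five deterministic
#' starting points spread over plausible values, keeping the best result.
#'
#' @param obs Observation table.
#' @param stage `"viability"` or `"germination"`.
#' @param alpha_max Optional fixed fraction at the optimum; default:
#'   observed control mean.
#' @param t_opt Optimal temperature (degrees C).
#' @return A `stage_fit` with estimates `theta1`, `theta2`.
#' @export
fit_fraction_surface <- function(obs, stage = c("viability", "germination"),
                                 alpha_max = NULL, t_opt = 18) {
  stage <- match.arg(stage)
  validate_observations(obs)
  means <- treatment_means(obs, stage)
  stop_if(nrow(means) == 0, "no ", stage, " observations")
  off_opt <- means[means$temperature_C != t_opt, , drop = FALSE]
  stop_if(nrow(off_opt) == 0,
          "all observations at the optimal temperature: surface unidentifiable")
  stop_if(length(unique(off_opt$duration_d)) < 2,
          "need >= 2 distinct durations away from the optimum")
  if (is.null(alpha_max)) {
    ctrl <- means$value[means$temperature_C == t_opt]
    stop_if(length(ctrl) == 0,
            "alpha_max unset and no control observations at the optimal temperature")
    alpha_max <- mean(ctrl)
  }
  stop_if(alpha_max <= 0 || alpha_max > 1, "alpha_max must lie in (0, 1]")
  sse <- function(theta) {
    sp <- fraction_surface_params(alpha_max, theta[1], theta[2], t_opt)
    pred <- fraction_surface(means$temperature_C, means$duration_d, sp)
    sum((means$value - pred)^2)
  }
  starts <- rbind(c(0.50, 0.00), c(0.75, -0.05), c(0.25, -0.10),
                  c(1.00, -0.15), c(0.00, -0.20))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- optim(starts[k, ], sse, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta_hat <- best$par
  sp_hat <- fraction_surface_params(alpha_max, theta_hat[1], theta_hat[2], t_opt)
  res <- data.frame(temperature_C = means$temperature_C,
                    duration_d = means$duration_d,
                    observed = means$value,
                    fitted = fraction_surface(means$temperature_C,
                                              means$duration_d, sp_hat))
  res$residual <- res$observed - res$fitted
  stage_fit(stage,
            c(theta1 = unname(theta_hat[1]), theta2 = unname(theta_hat[2])),
            fixed = list(alpha_max = alpha_max, t_opt = t_opt),
            residuals = res,
            convergence = list(method = "Nelder-Mead multistart (5 starts)",
                               objective = best$value,
                               converged = best$convergence == 0))
}
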