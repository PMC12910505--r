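# The user-facing model fit: thermofruit() estimates all five stages from
# an observation table and returns a classed object with the usual
# modelling methods (print, summary, coef, predict, residuals, plot,
# simulate).

#' Fit the temperature-response reproduction cascade
#'
#' Fits the five-stage cascade — pollen number, viability fraction,
#' germination fraction, seed number, fruit mass — to a tidy observation
#' table. Estimation follows the calibration protocol of the model: each
#' function is fitted individually and sequentially by least squares on
#' treatment means, with the cardinal temperatures held fixed and the
#' measured quantities (`n_star`, the two `alpha_max` fractions) taken
#' from the control treatment.
#'
#' The seed link is regressed on the observed germinated-pollen numbers
#' reconstructed from the pollen stages (treatment-mean pollen number
#' times treatment-mean viability and germination fractions), and the
#' mass link on observed treatment-mean seed numbers, exactly as the
#' calibration data were used.
#'
#' @param observations Observation table (see [validate_observations()]),
#'   e.g. from [simulate_experiment()] or [read_observations()].
#' @param fixed Named list of fixed temperatures `t_b`, `t_c`, `t_opt`,
#'   `t_0`.
#' @param n_star Optional fixed peak pollen number (default: observed
#'   control mean).
#' @param conversion A [conversion_params()] object.
#' @param fruit_set Optional [fruit_set_quad_params()] carried into the
#'   fitted parameter set (needed later for truss-level yield).
#' @return An object of class `thermofruit`: a list with components
#'   `params` (fitted [thermofruit_params()]), `stage_fits` (five
#'   `stage_fit` objects), `treatment_table` (observed vs fitted stage
#'   values per treatment), `rmse_per_function`, `rmse_aggregate`, and
#'   `call`.
#' @export
#' @examples
#' obs <- simulate_experiment(seed = 1)
#' fit <- thermofruit(obs)
#' fit
#' coef(fit)
#' predict(fit, newdata = data.frame(temperature = 30, duration = 4))
thermofruit <- function(observations,
                        fixed = list(t_b = 13, t_c = 48, t_opt = 18, t_0 = 1),
                        n_star = NULL,
                        conversion = conversion_params(),
                        fruit_set = NULL) {
  validate_observations(observations)
  t_opt <- fixed$t_opt

  fit_np <- fit_pollen_beta(observations, fixed = fixed, n_star = n_star,
                            conversion = conversion)
  fit_v <- fit_fraction_surface(observations, "viability", t_opt = t_opt)
  fit_g <- fit_fraction_surface(observations, "germination", t_opt = t_opt)

  # observed cascade reconstruction at treatment level for the two links
  np_means <- fit_np$residuals[, c("temperature_C", "observed")]
  names(np_means)[2] <- "n_pollen_obs"
  fv_means <- fit_v$residuals[, c("temperature_C", "duration_d", "observed")]
  names(fv_means)[3] <- "f_viable_obs"
  fg_means <- fit_g$residuals[, c("temperature_C", "duration_d", "observed")]
  names(fg_means)[3] <- "f_germ_obs"
  seed_means <- treatment_means(observations, "seed")
  names(seed_means)[names(seed_means) == "value"] <- "n_seeds_obs"
  mass_means <- treatment_means(observations, "fruit_mass")
  names(mass_means)[names(mass_means) == "value"] <- "fruit_mass_obs"

  tab <- merge(fv_means, fg_means, by = c("temperature_C", "duration_d"))
  tab <- merge(tab, np_means, by = "temperature_C")
  tab$n_germ_obs <- tab$n_pollen_obs * tab$f_viable_obs * tab$f_germ_obs
  tab <- merge(tab, seed_means, by = c("temperature_C", "duration_d"),
               all.x = TRUE)
  tab <- merge(tab, mass_means, by = c("temperature_C", "duration_d"),
               all.x = TRUE)

  link_rows <- tab[!is.na(tab$n_seeds_obs), , drop = FALSE]
  fit_seed <- fit_linear_link(link_rows$n_germ_obs * conversion$c_flower_to_fruit,
                              link_rows$n_seeds_obs, stage = "seed_number")
  mass_rows <- tab[!is.na(tab$n_seeds_obs) & !is.na(tab$fruit_mass_obs), ,
                   drop = FALSE]
  fit_mass <- fit_linear_link(mass_rows$n_seeds_obs, mass_rows$fruit_mass_obs,
                              stage = "fruit_mass")

  params <- thermofruit_params(
    pollen = pollen_beta_params(mu = fit_np$estimates[["mu"]],
                                n_star = fit_np$fixed$n_star,
                                t_b = fixed$t_b, t_c = fixed$t_c,
                                t_opt = t_opt, t_0 = fixed$t_0),
    viability = fraction_surface_params(fit_v$fixed$alpha_max,
                                        fit_v$estimates[["theta1"]],
                                        fit_v$estimates[["theta2"]], t_opt),
    germination = fraction_surface_params(fit_g$fixed$alpha_max,
                                          fit_g$estimates[["theta1"]],
                                          fit_g$estimates[["theta2"]], t_opt),
    seed_link = linear_link_params(fit_seed$estimates[["slope"]],
                                   fit_seed$estimates[["intercept"]]),
    mass_link = linear_link_params(fit_mass$estimates[["slope"]],
                                   fit_mass$estimates[["intercept"]]),
    conversion = conversion,
    fruit_set = fruit_set)

  # observed vs model stage values per treatment (basis of the summary RMSE)
  pred <- predict_cascade(tab$temperature_C, tab$duration_d, params,
                          warn = FALSE)
  treatment_table <- data.frame(
    temperature_C = tab$temperature_C, duration_d = tab$duration_d,
    n_pollen_obs = tab$n_pollen_obs, n_pollen_fit = pred$n_pollen,
    n_viable_obs = tab$n_pollen_obs * tab$f_viable_obs,
    n_viable_fit = pred$n_viable,
    n_germ_obs = tab$n_germ_obs, n_germ_fit = pred$n_germ,
    n_seeds_obs = tab$n_seeds_obs, n_seeds_fit = pred$n_seeds,
    fruit_mass_obs = tab$fruit_mass_obs, fruit_mass_fit = pred$fruit_mass_g)
  treatment_table <- treatment_table[order(treatment_table$temperature_C,
                                           treatment_table$duration_d), ]
  rownames(treatment_table) <- NULL

  stage_rmse <- function(o, f) {
    ok <- !is.na(o) & !is.na(f)
    if (!any(ok)) return(NA_real_)
    rmse(o[ok], f[ok])
  }
  rmse_per_function <- c(
    n_pollen = stage_rmse(treatment_table$n_pollen_obs, treatment_table$n_pollen_fit),
    n_viable = stage_rmse(treatment_table$n_viable_obs, treatment_table$n_viable_fit),
    n_germ = stage_rmse(treatment_table$n_germ_obs, treatment_table$n_germ_fit),
    n_seeds = stage_rmse(treatment_table$n_seeds_obs, treatment_table$n_seeds_fit),
    fruit_mass = stage_rmse(treatment_table$fruit_mass_obs,
                            treatment_table$fruit_mass_fit))

  structure(list(params = params,
                 stage_fits = list(pollen = fit_np, viability = fit_v,
                                   germination = fit_g, seed = fit_seed,
                                   mass = fit_mass),
                 treatment_table = treatment_table,
                 rmse_per_function = rmse_per_function,
                 # per-function values are reported alongside, so the
                 # mixed-units warning is not repeated here
                 rmse_aggregate = aggregate_rmse(rmse_per_function[!is.na(rmse_per_function)],
                                                 warn = FALSE),
                 call = match.call()),
            class = "thermofruit")
}

#' @export
print.thermofruit <- function(x, ...) {
  cat("Temperature-response reproduction cascade fit\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  print(round(coef(x), 6))
  cat(sprintf("\nPer-function RMSE (treatment means): %s\n",
              paste(sprintf("%s = %.4g", names(x$rmse_per_function),
                            x$rmse_per_function), collapse = ", ")))
  cat(sprintf("Aggregate RMSE (mean of the five; mixed units): %.4g\n",
              x$rmse_aggregate))
  invisible(x)
}

#' @export
coef.thermofruit <- function(object, ...) {
  p <- object$params
  sh <- derive_beta_shape(p$pollen)
  c(mu = p$pollen$mu, alpha = unname(sh["alpha"]), beta = unname(sh["beta"]),
    n_star = p$pollen$n_star,
    alpha_v = p$viability$alpha_max, theta_v1 = p$viability$theta1,
    theta_v2 = p$viability$theta2,
    alpha_g = p$germination$alpha_max, theta_g1 = p$germination$theta1,
    theta_g2 = p$germination$theta2,
    m1 = p$seed_link$slope, b1 = p$seed_link$intercept,
    m2 = p$mass_link$slope, b2 = p$mass_link$intercept)
}

#' @export
summary.thermofruit <- function(object, ...) {
  structure(list(fit = object), class = "summary.thermofruit")
}

#' @export
print.summary.thermofruit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nStage fits:\n")
  for (sf in fit$stage_fits) {
    cat(sprintf("  %-13s RMSE = %.4g, R^2 = %s, n = %d\n", sf$stage, sf$rmse,
                if (is.na(sf$r_squared)) "NA" else sprintf("%.3f", sf$r_squared),
                sf$n_obs))
  }
  cat("\nTreatment table (observed vs fitted):\n")
  print(fit$treatment_table, digits = 4)
  invisible(x)
}

#' Predict from a fitted cascade
#'
#' @param object A fitted `thermofruit` object.
#' @param newdata Data frame with columns `temperature` and `duration`
#'   (or `temperature_C`/`duration_d`); default: the fitted treatments.
#' @param type `"mass"` for fruit mass only, `"cascade"` for the full
#'   stage table.
#' @param ... Unused.
#' @return Numeric vector (`"mass"`) or data.frame (`"cascade"`).
#' @export
predict.thermofruit <- function(object, newdata = NULL,
                                type = c("mass", "cascade"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    temperature <- object$treatment_table$temperature_C
    duration <- object$treatment_table$duration_d
  } else {
    temperature <- if (!is.null(newdata$temperature)) newdata$temperature
                   else newdata$temperature_C
    duration <- if (!is.null(newdata$duration)) newdata$duration
                else newdata$duration_d
    stop_if(is.null(temperature) || is.null(duration),
            "newdata needs temperature and duration columns")
  }
  if (type == "mass") {
    predict_fruit_mass(temperature, duration, object$params)
  } else {
    predict_cascade(temperature, duration, object$params)
  }
}

#' Residuals of a fitted cascade
#'
#' @param object A fitted `thermofruit` object.
#' @param stage Optional stage name (`"pollen"`, `"viability"`,
#'   `"germination"`, `"seed"`, `"mass"`); default: all stages stacked.
#' @param ... Unused.
#' @return A data.frame of treatment-mean residuals with a `stage` column.
#' @export
residuals.thermofruit <- function(object, stage = NULL, ...) {
  fits <- object$stage_fits
  if (!is.null(stage)) fits <- fits[stage]
  out <- lapply(names(fits), function(nm) {
    r <- fits[[nm]]$residuals
    data.frame(stage = nm,
               temperature_C = if ("temperature_C" %in% names(r)) r$temperature_C else NA,
               duration_d = if ("duration_d" %in% names(r)) r$duration_d else NA,
               observed = r$observed, fitted = r$fitted,
               residual = r$observed - r$fitted)
  })
  do.call(rbind, out)
}

#' Plot a fitted cascade
#'
#' Four base-graphics panels: the fitted pollen-number temperature
#' response with treatment means; the viability and germination surfaces
#' as duration profiles per design temperature; and observed versus
#' predicted fruit mass with the 1:1 line.
#'
#' @param x A fitted `thermofruit` object.
#' @param which Which panels to draw (subset of 1:4).
#' @param ... Unused.
#' @export
plot.thermofruit <- function(x, which = 1:4, ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  nr <- if (length(which) > 2) 2 else 1
  nc <- ceiling(length(which) / nr)
  graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  p <- x$params
  tt <- x$treatment_table
  if (1 %in% which) {
    tg <- seq(p$pollen$t_b, p$pollen$t_c, length.out = 200)
    plot(tg, pollen_number(tg, p$pollen), type = "l",
         xlab = "Temperature (C)", ylab = "Pollen per flower",
         main = "Pollen number")
    graphics::points(tt$temperature_C, tt$n_pollen_obs, pch = 19)
  }
  surf_panel <- function(sp, obs_frac, main) {
    dg <- seq(0, 8, length.out = 100)
    temps <- sort(unique(tt$temperature_C))
    plot(NA, xlim = c(0, 8), ylim = c(0, 1), xlab = "Duration (d)",
         ylab = "Fraction", main = main)
    for (i in seq_along(temps)) {
      graphics::lines(dg, fraction_surface(temps[i], dg, sp), lty = i)
    }
    graphics::points(obs_frac$duration_d, obs_frac$observed,
                     pch = as.integer(factor(obs_frac$temperature_C)))
    graphics::legend("topright", legend = paste0(temps, " C"),
                     lty = seq_along(temps), cex = 0.7, bty = "n")
  }
  if (2 %in% which) surf_panel(p$viability, x$stage_fits$viability$residuals,
                               "Viability fraction")
  if (3 %in% which) surf_panel(p$germination, x$stage_fits$germination$residuals,
                               "Germination fraction")
  if (4 %in% which) {
    ok <- !is.na(tt$fruit_mass_obs)
    plot(tt$fruit_mass_fit[ok], tt$fruit_mass_obs[ok],
         xlab = "Predicted fruit mass (g)", ylab = "Observed fruit mass (g)",
         main = "Measured vs predicted", pch = 19)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Simulate observation tables from a fitted cascade
#'
#' Draws `nsim` synthetic experiments from the fitted parameter set using
#' the factorial-experiment generator, so a fit can be parametrically
#' bootstrapped or checked for self-consistency.
#'
#' @param object A fitted `thermofruit` object.
#' @param nsim Number of tables to draw.
#' @param seed Optional integer seed.
#' @param design An [experiment_design()] object.
#' @param noise A [noise_spec()] object.
#' @param ... Unused.
#' @return A list of `nsim` observation tables.
#' @export
simulate.thermofruit <- function(object, nsim = 1, seed = NULL,
                                 design = experiment_design(),
                                 noise = noise_spec(), ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s) {
    simulate_experiment(design = design, params = object$params,
                        noise = noise, seed = s)
  })
}
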