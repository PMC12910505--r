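# Deterministic five-stage cascade: temperature regime in, pollen number,
# viability/germination fractions, seed number, and fruit mass out.

#' Derive the beta-function shape exponents
#'
#' The pollen-number beta function is constrained so that it peaks at the
#' optimal temperature with value `n_star`. With scaled spans
#' `delta1 = (t_opt - t_b)/t_0`, `delta2 = (t_c - t_opt)/t_0` and
#' `delta3 = delta1/delta2`, the unique exponents satisfying that
#' constraint are
#' `beta = (log(n_star) - mu) / (delta3 * log(delta1) + log(delta2))` and
#' `alpha = beta * delta3`.
#'
#' @param params A [pollen_beta_params()] object.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @export
#' @examples
#' round(derive_beta_shape(pollen_beta_params()), 2)  # alpha 0.28, beta 1.66
derive_beta_shape <- function(params) {
  stopifnot(inherits(params, "pollen_beta_params"))
  d1 <- (params$t_opt - params$t_b) / params$t_0
  d2 <- (params$t_c - params$t_opt) / params$t_0
  d3 <- d1 / d2
  den <- d3 * log(d1) + log(d2)
  stop_if(!is.finite(den) || abs(den) < 1e-12,
          "degenerate beta-function parameterization: ",
          "delta3*log(delta1) + log(delta2) is zero")
  beta <- (log(params$n_star) - params$mu) / den
  c(alpha = beta * d3, beta = beta)
}

#' Pollen number per flower as a function of temperature
#'
#' Evaluates the constrained beta function
#' `exp(mu) * ((T - t_b)/t_0)^alpha * ((t_c - T)/t_0)^beta` for
#' temperatures strictly between the base and ceiling temperatures, and 0
#' outside that interval (including at the boundaries), which avoids
#' raising negative bases to real powers. Pollen number does not depend on
#' stress duration.
#'
#' @param temperature Temperature(s) in degrees C.
#' @param params A [pollen_beta_params()] object.
#' @return Pollen grains per flower, same length as `temperature`.
#' @export
pollen_number <- function(temperature, params) {
  stopifnot(inherits(params, "pollen_beta_params"),
            all(is.finite(temperature)))
  sh <- derive_beta_shape(params)
  out <- numeric(length(temperature))
  inside <- temperature > params$t_b & temperature < params$t_c
  if (any(inside)) {
    x <- (temperature[inside] - params$t_b) / params$t_0
    y <- (params$t_c - temperature[inside]) / params$t_0
    out[inside] <- exp(params$mu) * x^sh[["alpha"]] * y^sh[["beta"]]
  }
  out
}

#' Duration-interpolation level
#'
#' Latent anchor level of a fraction response surface as a function of
#' stress duration: `theta1 + theta2 * D^2`. The value may be negative
#' (the published viability fit reaches -0.98 at four days); clamping
#' happens downstream in [fraction_surface()].
#'
#' @param duration Stress duration(s) in days, non-negative.
#' @param theta1 Intercept (dimensionless).
#' @param theta2 Curvature (per day squared).
#' @return Latent level(s), same length as `duration`.
#' @export
duration_interpolation <- function(duration, theta1, theta2) {
  stop_if(any(duration < 0), "duration must be non-negative")
  theta1 + theta2 * duration^2
}

#' Fraction response surface over temperature and duration
#'
#' Quadratic surface in scaled temperature `u = T / t_opt` anchored at the
#' duration-interpolation level `p(D)`:
#' `f = clamp( p + 2 * (alpha_max - p) * u - (alpha_max - p) * u^2 )`.
#' The quadratic's vertex sits at `u = 1`, so the surface returns
#' `alpha_max` at the optimal temperature for every duration. The lower
#' clamp at 0 follows the model definition; the upper clamp at 1 is a
#' package design choice so that user-supplied parameters can never
#' produce a fraction above 1 and break the cascade ordering (with the
#' default parameters the surface never reaches 1).
#'
#' Used for both pollen viability and pollen germination by instantiating
#' the two parameter sets.
#'
#' @param temperature Temperature(s) in degrees C.
#' @param duration Stress duration(s) in days; recycled against
#'   `temperature`.
#' @param params A [fraction_surface_params()] object.
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' v <- fraction_surface_params(0.94, 0.78, -0.11)
#' fraction_surface(18, c(0, 4, 8), v)  # 0.94 at the optimum, any duration
fraction_surface <- function(temperature, duration, params) {
  stopifnot(inherits(params, "fraction_surface_params"),
            all(is.finite(temperature)))
  n <- max(length(temperature), length(duration))
  temperature <- rep_len(temperature, n)
  duration <- rep_len(duration, n)
  p <- duration_interpolation(duration, params$theta1, params$theta2)
  u <- temperature / params$t_opt
  # algebraically p + (alpha_max - p) * w with w = 2u - u^2, arranged so
  # the vertex at u = 1 returns alpha_max exactly in floating point
  w <- 2 * u - u * u
  latent <- p * (1 - w) + params$alpha_max * w
  pmin(1, pmax(0, latent))
}

#' Cascade stages: viable and germinated pollen per flower
#'
#' `viable_pollen()` multiplies the pollen number by the viability
#' fraction; `germinated_pollen()` multiplies the viable pollen by the
#' germination fraction. Because both fractions lie in \[0, 1\], the
#' cascade ordering `n_germ <= n_viable <= n_pollen` holds for every
#' regime.
#'
#' @param temperature,duration Temperature (degrees C) and stress duration
#'   (days); recycled to a common length.
#' @param params A [thermofruit_params()] object.
#' @return Pollen grains per flower.
#' @export
viable_pollen <- function(temperature, duration, params) {
  stopifnot(inherits(params, "thermofruit_params"))
  fraction_surface(temperature, duration, params$viability) *
    pollen_number(rep_len(temperature, max(length(temperature), length(duration))),
                  params$pollen)
}

#' @rdname viable_pollen
#' @export
germinated_pollen <- function(temperature, duration, params) {
  stopifnot(inherits(params, "thermofruit_params"))
  fraction_surface(temperature, duration, params$germination) *
    viable_pollen(temperature, duration, params)
}

#' Seed number per fruit from germinated pollen
#'
#' Linear link `slope * n_germinated * c_flower_to_fruit + intercept`.
#' The flower-to-fruit factor (default 1) carries the units contract
#' seeds/pollen x pollen/flower x flower/fruit = seeds/fruit.
#'
#' @param n_germinated Germinated pollen grains per flower (non-negative).
#' @param link A [linear_link_params()] object (seed link).
#' @param conversion A [conversion_params()] object.
#' @return Seeds per fruit.
#' @export
seed_number <- function(n_germinated, link, conversion = conversion_params()) {
  stopifnot(inherits(link, "linear_link_params"),
            inherits(conversion, "conversion_params"))
  stop_if(any(n_germinated < 0), "n_germinated must be non-negative")
  link$slope * n_germinated * conversion$c_flower_to_fruit + link$intercept
}

#' Individual fruit mass from seed number
#'
#' Linear link `slope * n_seeds + intercept`; the intercept is the
#' baseline mass of a seedless fruit.
#'
#' @param n_seeds Seeds per fruit (non-negative).
#' @param link A [linear_link_params()] object (mass link).
#' @return Fruit mass (grams per fruit by default labelling).
#' @export
fruit_mass <- function(n_seeds, link) {
  stopifnot(inherits(link, "linear_link_params"))
  stop_if(any(n_seeds < 0), "n_seeds must be non-negative")
  link$slope * n_seeds + link$intercept
}

#' Convert a haemocytometer grain count to pollen per flower
#'
#' `count / vol_chamber * vol_sample`, with the chamber volume in cubic mm
#' and the sample volume in microlitres (1 microlitre = 1 cubic mm). With
#' the default 0.2 cubic-mm chamber and 200 microlitre suspension, one
#' counted grain corresponds to 1000 grains per flower.
#'
#' @param count Grains counted in the chamber (non-negative).
#' @param conversion A [conversion_params()] object.
#' @return Pollen grains per flower.
#' @export
pollen_count_to_number <- function(count, conversion = conversion_params()) {
  stopifnot(inherits(conversion, "conversion_params"))
  stop_if(any(count < 0), "count must be non-negative")
  count / conversion$vol_chamber * conversion$vol_sample
}

# Calibrated envelope of the underlying experiment; predictions outside it
# are extrapolations and are flagged once per call.
calibrated_range <- list(temperature = c(14, 34), duration = c(0, 8))

warn_if_extrapolating <- function(temperature, duration) {
  out <- temperature < calibrated_range$temperature[1] |
    temperature > calibrated_range$temperature[2] |
    duration < calibrated_range$duration[1] |
    duration > calibrated_range$duration[2]
  if (any(out)) {
    warning(sprintf(
      "%d regime(s) outside the calibrated range T in [14, 34] C, D in [0, 8] d; predictions are extrapolations",
      sum(out)), call. = FALSE)
  }
  invisible(out)
}

#' Full cascade evaluation over temperature regimes
#'
#' `predict_cascade()` evaluates every stage of the cascade for a set of
#' (temperature, duration) regimes and returns a tidy table;
#' `predict_fruit_mass()` returns only the final stage. The composed
#' prediction is definitionally the step-by-step chain, so the two agree
#' bit for bit. Regimes outside the calibrated range (14-34 degrees C,
#' 0-8 days) are accepted with a warning.
#'
#' @param temperature,duration Temperature (degrees C) and stress duration
#'   (days, 0 for the unstressed control); recycled to a common length.
#' @param params A [thermofruit_params()] object.
#' @param warn Warn on regimes outside the calibrated range (default TRUE).
#' @return `predict_cascade()`: a data.frame with columns `temperature_C`,
#'   `duration_d`, `n_pollen`, `f_viable`, `n_viable`, `f_germ`, `n_germ`,
#'   `n_seeds`, `fruit_mass_g`. `predict_fruit_mass()`: a numeric vector.
#' @export
#' @examples
#' predict_cascade(c(18, 30, 34), c(0, 4, 4), thermofruit_params())
predict_cascade <- function(temperature, duration, params = thermofruit_params(),
                            warn = TRUE) {
  stopifnot(inherits(params, "thermofruit_params"))
  stop_if(any(duration < 0), "duration must be non-negative")
  stop_if(!all(is.finite(temperature)), "temperature must be finite")
  n <- max(length(temperature), length(duration))
  temperature <- rep_len(temperature, n)
  duration <- rep_len(duration, n)
  if (warn) warn_if_extrapolating(temperature, duration)
  n_pollen <- pollen_number(temperature, params$pollen)
  f_viable <- fraction_surface(temperature, duration, params$viability)
  n_viable <- f_viable * n_pollen
  f_germ <- fraction_surface(temperature, duration, params$germination)
  n_germ <- f_germ * n_viable
  n_seeds <- seed_number(n_germ, params$seed_link, params$conversion)
  mass <- fruit_mass(n_seeds, params$mass_link)
  data.frame(temperature_C = temperature, duration_d = duration,
             n_pollen = n_pollen, f_viable = f_viable, n_viable = n_viable,
             f_germ = f_germ, n_germ = n_germ, n_seeds = n_seeds,
             fruit_mass_g = mass)
}

#' @rdname predict_cascade
#' @export
predict_fruit_mass <- function(temperature, duration, params = thermofruit_params(),
                               warn = TRUE) {
  predict_cascade(temperature, duration, params, warn = warn)$fruit_mass_g
}

#' Fruit-set fraction from the user-supplied quadratic
#'
#' Evaluates `c0 + c1 * T + c2 * T^2` and clamps the result to \[0, 1\].
#' There are no shipped default coefficients; an explicit error is raised
#' when they are missing rather than silently assuming full fruit set.
#'
#' @param temperature Temperature(s) in degrees C.
#' @param fruit_set A [fruit_set_quad_params()] object.
#' @return Fruit-set fraction(s) in \[0, 1\].
#' @export
fruit_set_fraction <- function(temperature, fruit_set) {
  stop_if(is.null(fruit_set),
          "fruit-set coefficients required: supply fruit_set_quad_params()")
  stopifnot(inherits(fruit_set, "fruit_set_quad_params"))
  latent <- fruit_set$c0 + fruit_set$c1 * temperature + fruit_set$c2 * temperature^2
  pmin(1, pmax(0, latent))
}

#' Truss-level yield
#'
#' Yield per truss as the product of flower number, fruit-set fraction,
#' and predicted individual fruit mass:
#' `n_flowers * fruit_set_fraction(T) * predict_fruit_mass(T, D)`.
#'
#' @param temperature,duration Regime; recycled to a common length.
#' @param params A [thermofruit_params()] object.
#' @param fruit_set Optional [fruit_set_quad_params()] overriding
#'   `params$fruit_set`; required in one place or the other.
#' @param n_flowers Flowers per truss (default 9, the pruning level of the
#'   underlying experiment).
#' @param warn Warn on extrapolation (default TRUE).
#' @return Grams per truss.
#' @export
truss_yield <- function(temperature, duration, params = thermofruit_params(),
                        fruit_set = NULL, n_flowers = 9, warn = TRUE) {
  stop_if(any(n_flowers < 0), "n_flowers must be non-negative")
  fs <- if (is.null(fruit_set)) params$fruit_set else fruit_set
  frac <- fruit_set_fraction(temperature, fs)
  n_flowers * frac * predict_fruit_mass(temperature, duration, params, warn = warn)
}
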