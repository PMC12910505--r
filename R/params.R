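# Parameter containers for the reproduction cascade, plus configuration I/O.
# Every constructor validates its invariants up front so that model
# evaluation can assume well-formed inputs.

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

#' Pollen-number beta-function parameters
#'
#' Parameters of the constrained beta function that describes pollen number
#' per flower as a function of temperature. The curve rises from a base
#' temperature `t_b`, peaks at the optimum `t_opt` with value `n_star`
#' (pollen grains per flower), and falls to zero at a ceiling temperature
#' `t_c`. The two shape exponents of the beta function are not free
#' parameters: they are derived from the constraint that the curve attains
#' its maximum `n_star` exactly at `t_opt` (see [derive_beta_shape()]),
#' which leaves the magnitude parameter `mu` as the single free parameter
#' of the temperature response.
#'
#' Defaults are the published calibration for an indeterminate round tomato
#' cultivar grown at 18 degrees C.
#'
#' @param mu Magnitude parameter (dimensionless).
#' @param n_star Pollen number per flower at the optimal temperature.
#' @param t_b Base temperature (degrees C) below which no pollen is produced.
#' @param t_c Ceiling temperature (degrees C) above which no pollen is produced.
#' @param t_opt Optimal temperature (degrees C).
#' @param t_0 Scaling constant (degrees C, default 1) that makes temperature
#'   differences dimensionless; kept explicit rather than hard-coded.
#' @return An object of class `pollen_beta_params`.
#' @seealso [pollen_number()], [derive_beta_shape()]
#' @export
#' @examples
#' p <- pollen_beta_params()
#' derive_beta_shape(p)
pollen_beta_params <- function(mu = 5, n_star = 6.61e4,
                               t_b = 13, t_c = 48, t_opt = 18, t_0 = 1) {
  vals <- c(mu = mu, n_star = n_star, t_b = t_b, t_c = t_c,
            t_opt = t_opt, t_0 = t_0)
  stop_if(!all(is.finite(vals)), "all pollen-number parameters must be finite")
  stop_if(!(t_b < t_opt && t_opt < t_c),
          "temperatures must satisfy t_b < t_opt < t_c")
  stop_if(n_star <= 0, "n_star must be strictly positive")
  stop_if(t_0 <= 0, "t_0 must be strictly positive")
  structure(as.list(vals), class = "pollen_beta_params")
}

#' Fraction response-surface parameters
#'
#' Parameters of one quadratic temperature-by-duration response surface for
#' a pollen fraction (viability or germination). The surface is a quadratic
#' in scaled temperature `T / t_opt` whose vertex sits at the optimal
#' temperature with value `alpha_max`, anchored away from the optimum by a
#' duration-interpolation level `theta1 + theta2 * D^2`
#' (see [fraction_surface()]).
#'
#' @param alpha_max Fraction observed at the optimal temperature, in (0, 1].
#' @param theta1 Duration-interpolation intercept (dimensionless).
#' @param theta2 Duration-interpolation curvature (per day squared).
#'   Negative in the published fits, but the sign is not enforced.
#' @param t_opt Optimal temperature (degrees C); must be positive since the
#'   surface divides by it.
#' @return An object of class `fraction_surface_params`.
#' @export
fraction_surface_params <- function(alpha_max, theta1, theta2, t_opt = 18) {
  vals <- c(alpha_max = alpha_max, theta1 = theta1, theta2 = theta2,
            t_opt = t_opt)
  stop_if(!all(is.finite(vals)), "all surface parameters must be finite")
  stop_if(alpha_max <= 0 || alpha_max > 1, "alpha_max must lie in (0, 1]")
  stop_if(t_opt <= 0, "t_opt must be strictly positive")
  structure(as.list(vals), class = "fraction_surface_params")
}

#' Linear link parameters
#'
#' Slope/intercept pair for one of the two linear links of the cascade:
#' germinated pollen to seed number, or seed number to fruit mass.
#' A negative intercept is unusual for these links (the baselines are seeds
#' per seedless-pollination fruit and mass of a seedless fruit) and raises a
#' warning, not an error.
#'
#' @param slope Output units per input unit.
#' @param intercept Output units at zero input.
#' @return An object of class `linear_link_params`.
#' @export
linear_link_params <- function(slope, intercept) {
  stop_if(!all(is.finite(c(slope, intercept))),
          "slope and intercept must be finite")
  if (intercept < 0) {
    warning("negative intercept in linear link; the cascade floor no longer holds",
            call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept),
            class = "linear_link_params")
}

#' Measurement conversion constants
#'
#' Constants used to convert raw observations into model quantities: the
#' haemocytometer chamber volume and suspension sample volume that turn a
#' grain count into pollen per flower ([pollen_count_to_number()]), and the
#' flower-to-fruit conversion factor of the seed link (default 1: each
#' flower is assumed to develop into one fruit; abortion is handled
#' separately through the fruit-set fraction).
#'
#' @param c_flower_to_fruit Flowers per fruit (default 1).
#' @param vol_chamber Haemocytometer chamber volume in cubic mm (default 0.2).
#' @param vol_sample Suspension volume in microlitres (default 200).
#'   1 microlitre equals 1 cubic mm, so the two volumes share a unit.
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(c_flower_to_fruit = 1, vol_chamber = 0.2,
                              vol_sample = 200) {
  vals <- c(c_flower_to_fruit = c_flower_to_fruit,
            vol_chamber = vol_chamber, vol_sample = vol_sample)
  stop_if(!all(is.finite(vals)) || any(vals <= 0),
          "all conversion constants must be strictly positive")
  structure(as.list(vals), class = "conversion_params")
}

#' Fruit-set quadratic coefficients
#'
#' Coefficients of a quadratic in temperature returning the fruit-set
#' fraction (fraction of flowers that develop into a fruit). No default
#' coefficients are shipped: the published model reports point values of
#' the fruit-set response but not its fitted coefficients, so these are
#' always user-supplied. When evaluated the quadratic is clamped to
#' \[0, 1\]. A synthetic example configuration is installed at
#' `system.file("extdata", "fruit_set_synthetic_example.json", package = "thermofruit")`.
#'
#' @param c0,c1,c2 Intercept, linear, and quadratic coefficients of
#'   `c0 + c1 * T + c2 * T^2`.
#' @return An object of class `fruit_set_quad_params`.
#' @seealso [fruit_set_fraction()], [truss_yield()]
#' @export
fruit_set_quad_params <- function(c0, c1, c2) {
  stop_if(!all(is.finite(c(c0, c1, c2))),
          "fruit-set coefficients must be finite")
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "fruit_set_quad_params")
}

#' Full cascade parameter set
#'
#' Bundles the parameter groups of the five-stage cascade: pollen number
#' (beta function), viability surface, germination surface, seed link,
#' mass link, measurement conversions, and the optional fruit-set
#' quadratic. The defaults reproduce the published calibration exactly and
#' are also shipped as `inst/extdata/default_params.json`.
#'
#' The fruit-mass unit is carried as a metadata label (`mass_unit`,
#' default `"g"`) rather than converted: the source calibration labels
#' fruit mass in grams of dry matter in its parameter table but reports
#' fresh mass in its results, so the label is deliberately just a label.
#'
#' @param pollen [pollen_beta_params()] object.
#' @param viability,germination [fraction_surface_params()] objects.
#' @param seed_link Link from germinated pollen to seeds per fruit.
#' @param mass_link Link from seeds per fruit to fruit mass.
#' @param conversion [conversion_params()] object.
#' @param fruit_set Optional [fruit_set_quad_params()] object; `NULL` by
#'   default (required only for truss-level yield).
#' @param mass_unit Unit label for fruit mass outputs.
#' @return An object of class `thermofruit_params`.
#' @export
#' @examples
#' p <- thermofruit_params()
#' predict_cascade(c(18, 30), c(0, 4), p)
thermofruit_params <- function(pollen = pollen_beta_params(),
                               viability = fraction_surface_params(0.94, 0.78, -0.11),
                               germination = fraction_surface_params(0.31, 0.34, -0.06),
                               seed_link = linear_link_params(1.60e-3, 2.23),
                               mass_link = linear_link_params(7.80e-2, 2.06),
                               conversion = conversion_params(),
                               fruit_set = NULL,
                               mass_unit = "g") {
  stopifnot(inherits(pollen, "pollen_beta_params"),
            inherits(viability, "fraction_surface_params"),
            inherits(germination, "fraction_surface_params"),
            inherits(seed_link, "linear_link_params"),
            inherits(mass_link, "linear_link_params"),
            inherits(conversion, "conversion_params"))
  if (!is.null(fruit_set)) stopifnot(inherits(fruit_set, "fruit_set_quad_params"))
  structure(list(pollen = pollen, viability = viability,
                 germination = germination, seed_link = seed_link,
                 mass_link = mass_link, conversion = conversion,
                 fruit_set = fruit_set, mass_unit = mass_unit),
            class = "thermofruit_params")
}

#' @export
print.thermofruit_params <- function(x, ...) {
  sh <- derive_beta_shape(x$pollen)
  cat("Cascade parameter set (fruit mass in", x$mass_unit, "per fruit)\n")
  cat(sprintf("  pollen number : mu = %g, n* = %g at %g C (range %g-%g C); alpha = %.3f, beta = %.3f\n",
              x$pollen$mu, x$pollen$n_star, x$pollen$t_opt,
              x$pollen$t_b, x$pollen$t_c, sh[["alpha"]], sh[["beta"]]))
  cat(sprintf("  viability     : alpha_max = %g, p(D) = %g %+g D^2\n",
              x$viability$alpha_max, x$viability$theta1, x$viability$theta2))
  cat(sprintf("  germination   : alpha_max = %g, p(D) = %g %+g D^2\n",
              x$germination$alpha_max, x$germination$theta1, x$germination$theta2))
  cat(sprintf("  seed link     : %g * n_germ + %g seeds per fruit\n",
              x$seed_link$slope, x$seed_link$intercept))
  cat(sprintf("  mass link     : %g * n_seeds + %g %s per fruit\n",
              x$mass_link$slope, x$mass_link$intercept, x$mass_unit))
  cat(sprintf("  fruit set     : %s\n",
              if (is.null(x$fruit_set)) "not set (required only for truss yield)"
              else sprintf("%g %+g T %+g T^2 (clamped to [0,1])",
                           x$fruit_set$c0, x$fruit_set$c1, x$fruit_set$c2)))
  invisible(x)
}

# ---- configuration I/O -----------------------------------------------------

params_to_list <- function(params) {
  out <- lapply(unclass(params), function(g) {
    if (is.null(g) || !is.list(g)) g else unclass(g)
  })
  out
}

list_to_params <- function(x) {
  fs <- if (!is.null(x$fruit_set)) do.call(fruit_set_quad_params, x$fruit_set)
  thermofruit_params(
    pollen = do.call(pollen_beta_params, x$pollen),
    viability = do.call(fraction_surface_params, x$viability),
    germination = do.call(fraction_surface_params, x$germination),
    seed_link = do.call(linear_link_params, x$seed_link),
    mass_link = do.call(linear_link_params, x$mass_link),
    conversion = do.call(conversion_params, x$conversion),
    fruit_set = fs,
    mass_unit = if (is.null(x$mass_unit)) "g" else x$mass_unit)
}

config_format <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else stop("unrecognised config extension: ", ext, call. = FALSE)
}

#' Read or write a parameter configuration file
#'
#' Parameter sets round-trip through JSON or YAML (chosen by file
#' extension), one block per parameter group. The shipped default
#' configuration (`inst/extdata/default_params.json`) reproduces the
#' published calibration exactly.
#'
#' @param file Path to a `.json`, `.yaml`, or `.yml` file.
#' @param params A [thermofruit_params()] object (for writing).
#' @return `read_params()` returns a `thermofruit_params` object;
#'   `write_params()` returns `file` invisibly.
#' @export
read_params <- function(file) {
  x <- switch(config_format(file),
              json = jsonlite::read_json(file, simplifyVector = TRUE),
              yaml = yaml::read_yaml(file))
  list_to_params(x)
}

#' @rdname read_params
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "thermofruit_params"))
  x <- params_to_list(params)
  switch(config_format(file),
         json = jsonlite::write_json(x, file, auto_unbox = TRUE,
                                     digits = NA, null = "null", pretty = TRUE),
         yaml = yaml::write_yaml(x, file))
  invisible(file)
}
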