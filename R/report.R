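# Desk-scale reporting: response-surface grids, prediction tables, and
# the truss-level yield decomposition.

#' Response-surface grid
#'
#' Dense evaluation of one cascade quantity over a temperature x duration
#' grid, returned in long format (`temperature_C`, `duration_d`, `value`,
#' `quantity`) ready for CSV export or plotting. Grid values are computed
#' by the same cascade functions as any other prediction — there is no
#' cached surface to diverge from. The default axes cover the calibration
#' envelope.
#'
#' @param quantity One of `"viability"`, `"germination"`, `"pollen"`,
#'   `"fruit_mass"`.
#' @param params A [thermofruit_params()] object.
#' @param temperatures,durations Grid axis values (non-empty).
#' @return A long-format data.frame; the axis lengths are attached as
#'   attribute `grid_dim` (temperatures x durations).
#' @export
#' @examples
#' g <- surface_grid("viability", temperatures = c(14, 18, 30, 34),
#'                   durations = c(0, 1, 3, 4, 6))
#' subset(g, temperature_C == 18)  # vertex column: all 0.94
surface_grid <- function(quantity = c("viability", "germination", "pollen",
                                      "fruit_mass"),
                         params = thermofruit_params(),
                         temperatures = seq(14, 34, by = 1),
                         durations = c(0, 1, 3, 4, 6)) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(params, "thermofruit_params"))
  stop_if(length(temperatures) == 0 || length(durations) == 0,
          "empty grid axis")
  grid <- expand.grid(temperature_C = temperatures, duration_d = durations,
                      KEEP.OUT.ATTRS = FALSE)
  value <- switch(quantity,
    viability = fraction_surface(grid$temperature_C, grid$duration_d,
                                 params$viability),
    germination = fraction_surface(grid$temperature_C, grid$duration_d,
                                   params$germination),
    pollen = pollen_number(grid$temperature_C, params$pollen),
    fruit_mass = predict_fruit_mass(grid$temperature_C, grid$duration_d,
                                    params, warn = FALSE))
  out <- data.frame(temperature_C = grid$temperature_C,
                    duration_d = grid$duration_d,
                    value = value, quantity = quantity)
  attr(out, "grid_dim") <- c(length(temperatures), length(durations))
  out
}

#' Truss-level yield decomposition
#'
#' Per-regime table of the three factors of truss yield — predicted
#' individual fruit mass, fruit-set fraction, and flower number — and
#' their product. The decomposition separates the two routes by which
#' temperature stress reduces yield: smaller fruits (fewer seeds) versus
#' fewer fruits (lower fruit set).
#'
#' @param regimes Data frame with columns `temperature_C` and `duration_d`.
#' @param params A [thermofruit_params()] object.
#' @param fruit_set Optional [fruit_set_quad_params()] overriding
#'   `params$fruit_set`; required in one place or the other.
#' @param n_flowers Flowers per truss (default 9).
#' @param warn Warn on extrapolation.
#' @return Data frame with columns `temperature_C`, `duration_d`,
#'   `fruit_mass_g`, `fruit_set_fraction`, `n_flowers`,
#'   `yield_g_per_truss`.
#' @export
yield_decomposition <- function(regimes, params = thermofruit_params(),
                                fruit_set = NULL, n_flowers = 9,
                                warn = TRUE) {
  stopifnot(is.data.frame(regimes),
            all(c("temperature_C", "duration_d") %in% names(regimes)))
  fs <- if (is.null(fruit_set)) params$fruit_set else fruit_set
  stop_if(is.null(fs),
          "fruit-set coefficients required: supply fruit_set_quad_params()")
  mass <- predict_fruit_mass(regimes$temperature_C, regimes$duration_d,
                             params, warn = warn)
  frac <- fruit_set_fraction(regimes$temperature_C, fs)
  data.frame(temperature_C = regimes$temperature_C,
             duration_d = regimes$duration_d,
             fruit_mass_g = mass,
             fruit_set_fraction = frac,
             n_flowers = n_flowers,
             yield_g_per_truss = n_flowers * frac * mass)
}

#' Write cascade predictions to CSV
#'
#' Evaluates [predict_cascade()] for a set of regimes and writes the tidy
#' prediction table (`temperature_C`, `duration_d`, `n_pollen`,
#' `f_viable`, `n_viable`, `f_germ`, `n_germ`, `n_seeds`, `fruit_mass_g`).
#'
#' @param regimes Data frame with columns `temperature_C`, `duration_d`.
#' @param file Output CSV path.
#' @param params A [thermofruit_params()] object.
#' @return `file`, invisibly.
#' @export
write_predictions <- function(regimes, file, params = thermofruit_params()) {
  stopifnot(is.data.frame(regimes),
            all(c("temperature_C", "duration_d") %in% names(regimes)))
  pred <- predict_cascade(regimes$temperature_C, regimes$duration_d, params)
  utils::write.csv(pred, file, row.names = FALSE)
  invisible(file)
}
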