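# Synthetic factorial-experiment generator: observation tables with the
# statistical structure of the calibration experiment (10 treatments x 3
# blocks, pollen traits on 4 plants per block, fruit traits on 6, trusses
# 1-3, 9 flowers per truss), so estimation is testable without any
# external data.

#' Experimental design specification
#'
#' The default treatment list is the calibration design: an 18 degree C
#' control (duration 0), 14 degrees C for 4, 6, or 8 days, and 30 or 34
#' degrees C for 1, 3, or 4 days — ten treatments, three blocks
#' (repetitions of the experiment over time), pollen traits measured on
#' four plants per block and fruit traits on six, three trusses per
#' plant, nine flowers per truss.
#'
#' @param treatments Data frame with columns `temperature_C`, `duration_d`.
#' @param blocks Number of blocks.
#' @param plants_pollen Plants per block for pollen measurements.
#' @param plants_fruit Plants per block for fruit measurements.
#' @param trusses Trusses per plant.
#' @param flowers_per_truss Flowers per truss after pruning.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(treatments = default_treatments(),
                              blocks = 3, plants_pollen = 4, plants_fruit = 6,
                              trusses = 3, flowers_per_truss = 9) {
  stopifnot(is.data.frame(treatments),
            all(c("temperature_C", "duration_d") %in% names(treatments)))
  stop_if(any(treatments$duration_d < 0), "durations must be non-negative")
  counts <- c(blocks = blocks, plants_pollen = plants_pollen,
              plants_fruit = plants_fruit, trusses = trusses,
              flowers_per_truss = flowers_per_truss)
  stop_if(any(counts < 1) || any(counts != round(counts)),
          "design counts must be positive integers")
  structure(list(treatments = treatments, blocks = blocks,
                 plants_pollen = plants_pollen, plants_fruit = plants_fruit,
                 trusses = trusses, flowers_per_truss = flowers_per_truss),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @export
default_treatments <- function() {
  data.frame(
    temperature_C = c(18, 14, 14, 14, 30, 30, 30, 34, 34, 34),
    duration_d    = c(0,   4,  6,  8,  1,  3,  4,  1,  3,  4))
}

#' Observation noise specification
#'
#' Noise models layered on top of the deterministic cascade. Setting every
#' component to zero reproduces the cascade predictions exactly.
#'
#' * Haemocytometer counts: grains in the counted chamber volume are drawn
#'   around the expected count (true pollen number scaled by
#'   chamber/sample volume). `count_dispersion` 0 means no sampling, 1
#'   Poisson, and values above 1 a negative binomial with that
#'   variance-to-mean ratio (the true overdispersion of chamber counts is
#'   unknowable from summary data, so Poisson is the default and the
#'   negative-binomial switch is exposed).
#' * Viability: binomial on the grains actually counted in the chamber,
#'   mirroring that the measured fraction is a ratio of counted grains.
#' * Germination: binomial on `germination_n` grains scored per assay
#'   (the assay totals are not published; 150 is a plausible per-aliquot
#'   total and is configuration-exposed).
#' * Seeds: Poisson (or negative binomial) around the seed-link mean.
#' * Fruit mass: Gaussian with standard deviation `fruit_mass_sd` grams,
#'   truncated at zero. The 0.9 g default is a calibration choice that
#'   puts individual-fruit scatter on the order of the published
#'   whole-model error; it is not itself a published value.
#' * Blocks: optional multiplicative log-normal block effect of scale
#'   `block_sd` on pollen production (default 0: the cascade ignores
#'   blocks).
#'
#' @param count_dispersion Haemocytometer count dispersion (0 = none,
#'   1 = Poisson, >1 = negative binomial variance/mean ratio).
#' @param viability_sampling,germination_sampling,fruit_set_sampling 0 or
#'   1: toggle binomial sampling of the fractions.
#' @param seed_dispersion Seed-count dispersion, same convention as
#'   `count_dispersion`.
#' @param fruit_mass_sd Fruit-mass residual scale in grams.
#' @param block_sd Scale of the log-normal block effect on pollen number.
#' @param germination_n Grains scored per germination assay.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(count_dispersion = 1, viability_sampling = 1,
                       germination_sampling = 1, seed_dispersion = 1,
                       fruit_mass_sd = 0.9, block_sd = 0,
                       fruit_set_sampling = 1, germination_n = 150) {
  vals <- c(count_dispersion, viability_sampling, germination_sampling,
            seed_dispersion, fruit_mass_sd, block_sd, fruit_set_sampling,
            germination_n)
  stop_if(any(!is.finite(vals)) || any(vals < 0),
          "noise scales must be finite and non-negative")
  stop_if(germination_n < 1, "germination_n must be at least 1")
  structure(list(count_dispersion = count_dispersion,
                 viability_sampling = viability_sampling,
                 germination_sampling = germination_sampling,
                 seed_dispersion = seed_dispersion,
                 fruit_mass_sd = fruit_mass_sd,
                 block_sd = block_sd,
                 fruit_set_sampling = fruit_set_sampling,
                 germination_n = germination_n),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
zero_noise <- function() {
  noise_spec(count_dispersion = 0, viability_sampling = 0,
             germination_sampling = 0, seed_dispersion = 0,
             fruit_mass_sd = 0, block_sd = 0, fruit_set_sampling = 0)
}

# dispersed count draw: 0 = deterministic mean, 1 = Poisson, >1 = negative
# binomial with variance phi * mean
draw_counts <- function(n, mean, dispersion) {
  if (dispersion == 0) return(mean)
  if (dispersion == 1) return(stats::rpois(n, mean))
  size <- mean / (dispersion - 1)
  stats::rnbinom(n, size = size, mu = mean)
}

#' Generate a synthetic observation table
#'
#' Simulates one run of the factorial temperature-stress experiment under
#' a parameter truth and a noise model. For every plant x truss the
#' generative chain is: true pollen number from the beta function, grains
#' in the counted chamber volume drawn around the volume-scaled
#' expectation, viable grains binomial on the counted grains with the
#' surface viability fraction, germinated grains binomial on the assay
#' total with the surface germination fraction, seeds drawn around the
#' seed-link mean, and fruit mass Gaussian around the mass-link mean
#' (given the drawn seed count), truncated at zero. Fruit-set rows are
#' produced only when the truth carries fruit-set coefficients. The result
#' is deterministic under a fixed seed.
#'
#' @param design An [experiment_design()] object.
#' @param params A [thermofruit_params()] truth.
#' @param noise A [noise_spec()] object.
#' @param seed Optional integer seed.
#' @return A validated observation table (see [validate_observations()]).
#' @export
#' @examples
#' obs <- simulate_experiment(seed = 42)
#' table(obs$stage)
simulate_experiment <- function(design = experiment_design(),
                                params = thermofruit_params(),
                                noise = noise_spec(), seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "thermofruit_params"),
            inherits(noise, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  tr <- design$treatments
  truth <- predict_cascade(tr$temperature_C, tr$duration_d, params,
                           warn = FALSE)
  conv <- params$conversion
  block_effect <- if (noise$block_sd > 0) {
    exp(stats::rnorm(design$blocks, 0, noise$block_sd))
  } else rep(1, design$blocks)

  pollen_grid <- expand.grid(trt = seq_len(nrow(tr)),
                             block = seq_len(design$blocks),
                             plant = seq_len(design$plants_pollen),
                             truss = seq_len(design$trusses))
  n_p <- nrow(pollen_grid)
  n_true <- truth$n_pollen[pollen_grid$trt] * block_effect[pollen_grid$block]
  expected_count <- n_true * conv$vol_chamber / conv$vol_sample
  counts <- draw_counts(n_p, expected_count, noise$count_dispersion)

  f_v <- truth$f_viable[pollen_grid$trt]
  if (noise$viability_sampling > 0) {
    denom_v <- pmax(round(counts), 0)
    k_v <- ifelse(denom_v > 0, stats::rbinom(n_p, denom_v, f_v), NA_real_)
    viab <- ifelse(denom_v > 0, k_v / denom_v, NA_real_)
  } else {
    denom_v <- counts
    viab <- f_v
  }

  f_g <- truth$f_germ[pollen_grid$trt]
  if (noise$germination_sampling > 0) {
    denom_g <- rep(noise$germination_n, n_p)
    germ <- stats::rbinom(n_p, denom_g, f_g) / denom_g
  } else {
    denom_g <- rep(noise$germination_n, n_p)
    germ <- f_g
  }

  base_pollen <- data.frame(
    temperature_C = tr$temperature_C[pollen_grid$trt],
    duration_d = tr$duration_d[pollen_grid$trt],
    block = pollen_grid$block, plant = pollen_grid$plant,
    truss = pollen_grid$truss)
  rows <- list(
    cbind(base_pollen, stage = "pollen_count", value = counts,
          denominator = NA_real_),
    cbind(base_pollen, stage = "viability", value = viab,
          denominator = denom_v),
    cbind(base_pollen, stage = "germination", value = germ,
          denominator = denom_g))

  fruit_grid <- expand.grid(trt = seq_len(nrow(tr)),
                            block = seq_len(design$blocks),
                            plant = seq_len(design$plants_fruit),
                            truss = seq_len(design$trusses))
  n_f <- nrow(fruit_grid)
  seed_mean <- truth$n_seeds[fruit_grid$trt]
  seeds <- draw_counts(n_f, seed_mean, noise$seed_dispersion)
  mass_mean <- fruit_mass(seeds, params$mass_link)
  mass <- if (noise$fruit_mass_sd > 0) {
    pmax(stats::rnorm(n_f, mass_mean, noise$fruit_mass_sd), 1e-6)
  } else mass_mean
  base_fruit <- data.frame(
    temperature_C = tr$temperature_C[fruit_grid$trt],
    duration_d = tr$duration_d[fruit_grid$trt],
    block = fruit_grid$block, plant = fruit_grid$plant,
    truss = fruit_grid$truss)
  rows <- c(rows, list(
    cbind(base_fruit, stage = "seed", value = seeds, denominator = NA_real_),
    cbind(base_fruit, stage = "fruit_mass", value = mass,
          denominator = NA_real_)))

  if (!is.null(params$fruit_set)) {
    fs_true <- fruit_set_fraction(tr$temperature_C[fruit_grid$trt],
                                  params$fruit_set)
    fs <- if (noise$fruit_set_sampling > 0) {
      stats::rbinom(n_f, design$flowers_per_truss, fs_true) /
        design$flowers_per_truss
    } else fs_true
    rows <- c(rows, list(
      cbind(base_fruit, stage = "fruit_set", value = fs,
            denominator = design$flowers_per_truss)))
  }

  obs <- do.call(rbind, rows)
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  rownames(obs) <- NULL
  validate_observations(obs, design)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates a synthetic experiment under a known truth and
#' refits the cascade, reporting per-parameter recovery error for the
#' estimated parameters (`mu`, the four interpolation thetas, and the two
#' link slope/intercept pairs). Fit failures are counted and reported,
#' not fatal.
#'
#' @param n_runs Number of Monte-Carlo replicates (>= 1).
#' @param design An [experiment_design()] object.
#' @param params The [thermofruit_params()] truth.
#' @param noise A [noise_spec()] object.
#' @param seed Integer seed for the study.
#' @param tolerance Relative-error threshold reported as coverage.
#' @return An object of class `recovery_study`: list with `summary` (one
#'   row per parameter: truth, median absolute relative error, fraction of
#'   runs within `tolerance`), `estimates` (per-run estimates), `n_failed`.
#' @export
recovery_study <- function(n_runs, design = experiment_design(),
                           params = thermofruit_params(),
                           noise = noise_spec(), seed = 1,
                           tolerance = 0.10) {
  stop_if(length(n_runs) != 1 || n_runs < 1 || n_runs != round(n_runs),
          "n_runs must be a positive integer")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  tracked <- c("mu", "theta_v1", "theta_v2", "theta_g1", "theta_g2",
               "m1", "b1", "m2", "b2")
  truth <- coef_truth(params)[tracked]
  ests <- matrix(NA_real_, nrow = n_runs, ncol = length(tracked),
                 dimnames = list(NULL, tracked))
  n_failed <- 0L
  for (i in seq_len(n_runs)) {
    obs <- simulate_experiment(design, params, noise, seed = run_seeds[i])
    fit <- tryCatch(thermofruit(obs,
                                fixed = list(t_b = params$pollen$t_b,
                                             t_c = params$pollen$t_c,
                                             t_opt = params$pollen$t_opt,
                                             t_0 = params$pollen$t_0)),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    ests[i, ] <- coef(fit)[tracked]
  }
  rel_err <- sweep(sweep(ests, 2, truth, "-"), 2, truth, "/")
  summ <- data.frame(
    parameter = tracked,
    truth = unname(truth),
    median_abs_rel_error = apply(abs(rel_err), 2, stats::median, na.rm = TRUE),
    frac_within_tol = apply(abs(rel_err) <= tolerance, 2, mean, na.rm = TRUE),
    row.names = NULL)
  structure(list(summary = summ, estimates = as.data.frame(ests),
                 n_runs = n_runs, n_failed = n_failed,
                 tolerance = tolerance),
            class = "recovery_study")
}

coef_truth <- function(params) {
  c(mu = params$pollen$mu,
    theta_v1 = params$viability$theta1, theta_v2 = params$viability$theta2,
    theta_g1 = params$germination$theta1, theta_g2 = params$germination$theta2,
    m1 = params$seed_link$slope, b1 = params$seed_link$intercept,
    m2 = params$mass_link$slope, b2 = params$mass_link$intercept)
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter-recovery study: %d runs (%d failed fits)\n",
              x$n_runs, x$n_failed))
  cat(sprintf("Coverage threshold: |relative error| <= %g\n\n", x$tolerance))
  print(x$summary, digits = 3)
  invisible(x)
}
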