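test_that("default design reproduces the factorial experiment structure", {
  d <- experiment_design()
  expect_equal(nrow(d$treatments), 10)
  expect_equal(sort(unique(d$treatments$temperature_C)), c(14, 18, 30, 34))
  expect_equal(d$treatments$duration_d[d$treatments$temperature_C == 14],
               c(4, 6, 8))
  expect_equal(d$treatments$duration_d[d$treatments$temperature_C == 30],
               c(1, 3, 4))
  expect_equal(d$blocks, 3)
  expect_equal(d$plants_pollen, 4)
  expect_equal(d$plants_fruit, 6)
  expect_equal(d$trusses, 3)
  expect_equal(d$flowers_per_truss, 9)
  expect_error(experiment_design(blocks = 0), "positive integers")
  expect_error(noise_spec(fruit_mass_sd = -1), "non-negative")
})

test_that("simulated tables have the declared replication per stage", {
  obs <- simulate_experiment(seed = 2)
  validate_observations(obs, experiment_design())
  counts <- table(obs$stage)
  expect_equal(unname(counts[["pollen_count"]]), 10 * 3 * 4 * 3)
  expect_equal(unname(counts[["viability"]]), 10 * 3 * 4 * 3)
  expect_equal(unname(counts[["germination"]]), 10 * 3 * 4 * 3)
  expect_equal(unname(counts[["seed"]]), 10 * 3 * 6 * 3)
  expect_equal(unname(counts[["fruit_mass"]]), 10 * 3 * 6 * 3)
  expect_false("fruit_set" %in% names(counts))   # no coefficients shipped
  # all 10 treatments x 3 blocks present
  expect_equal(nrow(unique(obs[, c("temperature_C", "duration_d")])), 10)
  expect_equal(sort(unique(obs$block)), 1:3)
})

test_that("a fixed seed reproduces the table; different seeds differ", {
  a <- simulate_experiment(seed = 99)
  b <- simulate_experiment(seed = 99)
  c_ <- simulate_experiment(seed = 100)
  expect_identical(a, b)
  expect_false(identical(a, c_))
})

test_that("zero noise reproduces the deterministic cascade exactly", {
  obs <- sim_noise_free()
  truth <- predict_cascade(obs$temperature_C, obs$duration_d, tf_params,
                           warn = FALSE)
  conv <- tf_params$conversion
  i <- obs$stage == "pollen_count"
  expect_equal(pollen_count_to_number(obs$value[i], conv), truth$n_pollen[i],
               tolerance = 1e-12)
  i <- obs$stage == "viability"
  expect_equal(obs$value[i], truth$f_viable[i], tolerance = 1e-12)
  i <- obs$stage == "germination"
  expect_equal(obs$value[i], truth$f_germ[i], tolerance = 1e-12)
  i <- obs$stage == "seed"
  expect_equal(obs$value[i], truth$n_seeds[i], tolerance = 1e-12)
  i <- obs$stage == "fruit_mass"
  expect_equal(obs$value[i], truth$fruit_mass_g[i], tolerance = 1e-12)
})

test_that("simulated tables preserve the cascade ordering row-wise", {
  obs <- simulate_experiment(seed = 31)
  key <- paste(obs$temperature_C, obs$duration_d, obs$block, obs$plant,
               obs$truss)
  counts <- obs[obs$stage == "pollen_count", ]
  viab <- obs[obs$stage == "viability", ]
  germ <- obs[obs$stage == "germination", ]
  m <- match(paste(viab$temperature_C, viab$duration_d, viab$block,
                   viab$plant, viab$truss),
             paste(counts$temperature_C, counts$duration_d, counts$block,
                   counts$plant, counts$truss))
  n_pollen <- pollen_count_to_number(counts$value[m])
  n_viable <- viab$value * n_pollen
  n_germ <- germ$value * n_viable
  expect_true(all(n_germ >= 0))
  expect_true(all(n_germ <= n_viable + 1e-9))
  expect_true(all(n_viable <= n_pollen + 1e-9))
})

test_that("simulated fraction means converge to the surface values", {
  # empirical mean viability at one stressed treatment across replicates
  target <- fraction_surface(30, 3, tf_params$viability)
  sims <- vapply(1:30, function(s) {
    obs <- simulate_experiment(seed = 1000 + s)
    rows <- obs$stage == "viability" & obs$temperature_C == 30 &
      obs$duration_d == 3
    mean(obs$value[rows])
  }, numeric(1))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - target), 4 * se + 0.005)
})

test_that("negative-binomial count switch inflates count dispersion", {
  over <- noise_spec(count_dispersion = 8)
  a <- simulate_experiment(noise = over, seed = 4)
  b <- simulate_experiment(seed = 4)
  va <- var(a$value[a$stage == "pollen_count" & a$temperature_C == 18])
  vb <- var(b$value[b$stage == "pollen_count" & b$temperature_C == 18])
  expect_gt(va, 2 * vb)
})

test_that("fruit-set rows appear only when coefficients are supplied", {
  p <- thermofruit_params(fruit_set = fruit_set_quad_params(-0.35, 0.1041667,
                                                            -0.0020833))
  obs <- simulate_experiment(params = p, seed = 8)
  fs <- obs[obs$stage == "fruit_set", ]
  expect_equal(nrow(fs), 10 * 3 * 6 * 3)
  expect_true(all(fs$value >= 0 & fs$value <= 1))
  expect_true(all(fs$denominator == 9))
})

test_that("observation tables round-trip through CSV with validation", {
  obs <- simulate_experiment(seed = 6)
  file <- tempfile(fileext = ".csv")
  write_observations(obs, file)
  back <- read_observations(file)
  expect_equal(back$value, obs$value, tolerance = 1e-12)
  expect_equal(back$stage, obs$stage)
  unlink(file)
  bad <- obs
  bad$value[bad$stage == "viability"][1] <- 2
  expect_error(validate_observations(bad), "\\[0, 1\\]")
  bad2 <- obs
  bad2$temperature_C[1] <- 99
  expect_error(validate_observations(bad2, experiment_design()),
               "outside the declared design")
})

test_that("recovery study reports per-parameter errors and rejects n_runs < 1", {
  expect_error(recovery_study(0), "positive integer")
  rs <- recovery_study(1, noise = zero_noise(), seed = 12)
  expect_s3_class(rs, "recovery_study")
  expect_equal(rs$n_failed, 0)
  expect_true(all(rs$summary$median_abs_rel_error < 1e-4))
  expect_true(all(rs$summary$frac_within_tol == 1))
  out <- capture.output(print(rs))
  expect_true(any(grepl("1 runs", out)))
})
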