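test_that("rmse obeys its hand-checkable identities", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_equal(rmse(rep(5, 7), rep(5, 7) - 3), 3)
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_warning(aggregate_rmse(c(1, 2, 3)), "different units")
  expect_equal(aggregate_rmse(c(1, 2, 3), warn = FALSE), 2)
  expect_error(aggregate_rmse(c(-1, 2), warn = FALSE), "non-negative")
})

test_that("r_squared spans perfect, mean-level, and worse-than-mean fits", {
  obs <- c(1, 3, 5, 9)
  expect_identical(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_lt(r_squared(obs, rev(obs)), 0)
  expect_error(r_squared(rep(2, 4), 1:4), "zero total variance")
  expect_error(r_squared(1, 1), "at least two")
})

test_that("linear link fit recovers an exact generating line", {
  x <- c(0, 5000, 12000, 19000, 25000)
  y <- 1.60e-3 * x + 2.23
  fit <- fit_linear_link(x, y)
  expect_equal(unname(fit$estimates["slope"]), 1.60e-3, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["intercept"]), 2.23, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  expect_equal(nrow(fit$residuals), length(x))
})

test_that("linear link fit handles the degenerate cases by convention", {
  # constant response: slope 0, intercept mean, R^2 defined as 0
  fit <- fit_linear_link(c(1, 2, 3, 4), rep(7, 4))
  expect_identical(unname(fit$estimates), c(0, 7))
  expect_identical(fit$r_squared, 0)
  expect_error(fit_linear_link(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_linear_link(rep(2, 5), 1:5), "zero predictor variance")
})

test_that("pollen beta fit recovers mu from noise-free data", {
  obs <- sim_noise_free()
  fit <- fit_pollen_beta(obs)
  expect_equal(unname(fit$estimates["mu"]), 5, tolerance = 1e-5)
  expect_equal(fit$fixed$n_star, 6.61e4, tolerance = 1e-8)
  expect_equal(fit$rmse, 0, tolerance = 1e-3)
  expect_equal(nrow(fit$residuals), 4)   # one treatment mean per temperature
})

test_that("pollen beta fit agrees with an exhaustive grid-search oracle", {
  obs <- simulate_experiment(seed = 11)   # default calibrated noise
  fit <- fit_pollen_beta(obs)
  # independent oracle: brute-force scan of the same least-squares surface
  rows <- obs[obs$stage == "pollen_count", ]
  rows$value <- pollen_count_to_number(rows$value)
  means <- aggregate(rows["value"], list(temperature_C = rows$temperature_C),
                     mean)
  n_star <- means$value[means$temperature_C == 18]
  sse <- vapply(seq(0, 15, by = 0.001), function(mu) {
    p <- pollen_beta_params(mu = mu, n_star = n_star)
    sum((means$value - pollen_number(means$temperature_C, p))^2)
  }, numeric(1))
  mu_grid <- seq(0, 15, by = 0.001)[which.min(sse)]
  expect_lt(abs(unname(fit$estimates["mu"]) - mu_grid), 0.001)
})

test_that("pollen beta fit rejects degenerate designs", {
  obs <- sim_noise_free()
  one_temp <- obs[obs$temperature_C == 30, ]
  expect_error(fit_pollen_beta(one_temp), ">= 3 distinct temperatures")
  no_ctrl <- obs[obs$temperature_C != 18, ]
  expect_error(fit_pollen_beta(no_ctrl), "optimal temperature")
  # but an explicit n_star rescues a design without control observations
  fit <- fit_pollen_beta(no_ctrl, n_star = 6.61e4)
  expect_equal(unname(fit$estimates["mu"]), 5, tolerance = 1e-4)
})

test_that("fraction surface fits recover both theta pairs from noise-free data", {
  obs <- sim_noise_free()
  fv <- fit_fraction_surface(obs, "viability")
  expect_equal(unname(fv$estimates), c(0.78, -0.11), tolerance = 1e-4)
  expect_equal(fv$fixed$alpha_max, 0.94, tolerance = 1e-10)
  expect_equal(fv$rmse, 0, tolerance = 1e-6)
  fg <- fit_fraction_surface(obs, "germination")
  expect_equal(unname(fg$estimates), c(0.34, -0.06), tolerance = 1e-4)
  expect_equal(fg$fixed$alpha_max, 0.31, tolerance = 1e-10)
})

test_that("fraction surface fit validates inputs and identifiability", {
  obs <- sim_noise_free()
  only_opt <- obs[obs$temperature_C == 18, ]
  expect_error(fit_fraction_surface(only_opt, "viability"), "unidentifiable")
  bad <- obs
  bad$value[which(bad$stage == "viability")[1]] <- 1.2
  expect_error(fit_fraction_surface(bad, "viability"), "\\[0, 1\\]")
})

test_that("fits are invariant to row order and block/truss relabelling", {
  obs <- simulate_experiment(seed = 5)
  shuffled <- obs[rev(seq_len(nrow(obs))), ]
  relabelled <- shuffled
  relabelled$block <- relabelled$block + 10
  relabelled$truss <- 4 - relabelled$truss
  f1 <- thermofruit(obs)
  f2 <- thermofruit(relabelled)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})
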