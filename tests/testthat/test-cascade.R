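test_that("beta-shape derivation matches the constraint formulas", {
  sh <- derive_beta_shape(tf_params$pollen)
  expect_equal(unname(sh["beta"]), oracle$beta, tolerance = 1e-12)
  expect_equal(unname(sh["alpha"]), oracle$alpha, tolerance = 1e-12)
  # flat-exponent limit: mu = log(n_star) zeroes both exponents
  flat <- derive_beta_shape(pollen_beta_params(mu = log(6.61e4)))
  expect_equal(unname(flat), c(0, 0))
  # degenerate denominator: delta3*log(delta1) + log(delta2) = 0
  # (t_opt - t_b = 1 makes log(delta1) = 0; delta2 = 1 makes log(delta2) = 0)
  expect_error(derive_beta_shape(pollen_beta_params(t_b = 17, t_c = 19)),
               "degenerate")
})

test_that("pollen number peaks at n_star, vanishes at the cardinal bounds", {
  p <- tf_params$pollen
  expect_equal(pollen_number(18, p), 6.61e4, tolerance = 1e-12)
  expect_identical(pollen_number(c(13, 48), p), c(0, 0))
  expect_identical(pollen_number(c(5, 60), p), c(0, 0))
  expect_equal(pollen_number(30, p), oracle$n_pollen_30, tolerance = 1e-12)
  # peak identity holds for arbitrary valid parameterizations
  for (mu in c(2, 5, 9)) {
    for (tb in c(8, 13)) {
      q <- pollen_beta_params(mu = mu, n_star = 3e4, t_b = tb, t_c = 45,
                              t_opt = 20)
      expect_equal(pollen_number(20, q), 3e4, tolerance = 1e-9)
      expect_identical(pollen_number(c(tb, 45), q), c(0, 0))
    }
  }
})

test_that("fitted pollen response declines faster on the cold side", {
  p <- tf_params$pollen
  expect_equal(pollen_number(14, p), oracle$n_pollen_14, tolerance = 1e-12)
  expect_equal(pollen_number(22, p), oracle$n_pollen_22, tolerance = 1e-12)
  expect_lt(pollen_number(14, p), pollen_number(22, p))
})

test_that("duration interpolation is a plain quadratic, latent values may be negative", {
  expect_equal(duration_interpolation(0, 0.78, -0.11), 0.78)
  expect_equal(duration_interpolation(4, 0.78, -0.11), -0.98)
  expect_equal(duration_interpolation(4, 0.34, -0.06), -0.62)
  expect_error(duration_interpolation(-1, 0.78, -0.11), "non-negative")
})

test_that("fraction surface returns alpha_max at the optimum for every duration", {
  for (d in c(0, 1, 3, 4, 6, 8)) {
    expect_identical(fraction_surface(18, d, tf_params$viability), 0.94)
    expect_identical(fraction_surface(18, d, tf_params$germination), 0.31)
  }
  expect_equal(fraction_surface(30, 4, tf_params$viability),
               oracle$f_viable_30_4, tolerance = 1e-12)
  # negative latent values clamp to zero
  expect_identical(fraction_surface(34, 6, tf_params$germination), 0)
  expect_identical(fraction_surface(34, 4, tf_params$viability), 0)
  # upper clamp guards user parameterizations that overshoot 1
  hot <- fraction_surface_params(1, 2, 0)
  expect_lte(max(fraction_surface(seq(0, 40, 0.5), 2, hot)), 1)
})

test_that("fraction surface is non-increasing in duration off-optimum when theta2 < 0", {
  durations <- seq(0, 8, by = 0.25)
  for (temp in c(14, 25, 30, 34)) {
    for (sp in list(tf_params$viability, tf_params$germination)) {
      f <- fraction_surface(temp, durations, sp)
      expect_true(all(diff(f) <= 1e-12))
    }
  }
})

test_that("cascade stages multiply and preserve ordering", {
  expect_equal(viable_pollen(18, 0, tf_params), 0.94 * 6.61e4)
  expect_identical(viable_pollen(13, 5, tf_params), 0)
  expect_equal(germinated_pollen(18, 0, tf_params), oracle$n_germ_control)
  nv <- viable_pollen(14, 4, tf_params)
  ng <- germinated_pollen(14, 4, tf_params)
  expect_gt(ng, 0)
  expect_lt(ng, nv)
  # 50 x 20 regime grid: 0 <= n_germ <= n_viable <= n_pollen everywhere
  grid <- expand.grid(temp = seq(0, 50, length.out = 50),
                      dur = seq(0, 8, length.out = 20))
  np <- pollen_number(grid$temp, tf_params$pollen)
  nv <- viable_pollen(grid$temp, grid$dur, tf_params)
  ng <- germinated_pollen(grid$temp, grid$dur, tf_params)
  expect_true(all(ng >= 0))
  expect_true(all(ng <= nv + 1e-9))
  expect_true(all(nv <= np + 1e-9))
})

test_that("linear links and their intercept floors", {
  expect_equal(seed_number(0, tf_params$seed_link), 2.23)
  expect_equal(seed_number(1e4, tf_params$seed_link), 18.23)
  expect_equal(seed_number(oracle$n_germ_control, tf_params$seed_link),
               oracle$n_seeds_control, tolerance = 1e-12)
  expect_equal(fruit_mass(0, tf_params$mass_link), 2.06)
  expect_equal(fruit_mass(20, tf_params$mass_link), 3.62)
  expect_error(seed_number(-1, tf_params$seed_link), "non-negative")
  expect_error(fruit_mass(-1, tf_params$mass_link), "non-negative")
  # flower-to-fruit factor is a plain product in the seed link
  conv2 <- conversion_params(c_flower_to_fruit = 2)
  expect_equal(seed_number(1e4, tf_params$seed_link, conv2),
               1.6e-3 * 1e4 * 2 + 2.23)
})

test_that("composed prediction equals the step-by-step chain bit for bit", {
  grid <- expand.grid(temp = seq(14, 34, length.out = 15),
                      dur = c(0, 1, 3, 4, 6, 8))
  chain <- fruit_mass(
    seed_number(germinated_pollen(grid$temp, grid$dur, tf_params),
                tf_params$seed_link, tf_params$conversion),
    tf_params$mass_link)
  expect_identical(predict_fruit_mass(grid$temp, grid$dur, tf_params), chain)
  # cascade table is internally consistent
  tab <- predict_cascade(grid$temp, grid$dur, tf_params)
  expect_identical(tab$n_viable, tab$f_viable * tab$n_pollen)
  expect_identical(tab$n_germ, tab$f_germ * tab$n_viable)
  expect_identical(tab$fruit_mass_g, chain)
})

test_that("fruit mass is floored at the seedless baseline", {
  expect_equal(predict_fruit_mass(18, 0, tf_params), oracle$mass_control,
               tolerance = 1e-12)
  grid <- expand.grid(temp = seq(0, 50, length.out = 40),
                      dur = seq(0, 8, length.out = 10))
  mass <- predict_fruit_mass(grid$temp, grid$dur, tf_params, warn = FALSE)
  expect_true(all(mass >= 2.06))
  # full germination collapse leaves exactly the two intercepts
  expect_equal(predict_fruit_mass(34, 6, tf_params),
               7.80e-2 * 2.23 + 2.06, tolerance = 1e-12)
})

test_that("regimes outside the calibrated envelope warn but evaluate", {
  expect_warning(predict_cascade(40, 2, tf_params), "extrapolation")
  expect_warning(predict_cascade(20, 10, tf_params), "extrapolation")
  expect_silent(predict_cascade(c(14, 34), c(0, 4), tf_params))
  expect_equal(suppressWarnings(predict_fruit_mass(-5, 0, tf_params)),
               7.80e-2 * 2.23 + 2.06)
})

test_that("haemocytometer conversion scales count by sample/chamber volume", {
  expect_identical(pollen_count_to_number(0), 0)
  expect_equal(pollen_count_to_number(13), 13000)
  expect_equal(pollen_count_to_number(66.1), 6.61e4)
  expect_equal(pollen_count_to_number(10, conversion_params(vol_chamber = 0.5,
                                                            vol_sample = 100)),
               2000)
  expect_error(pollen_count_to_number(-1), "non-negative")
})

test_that("truss yield needs fruit-set coefficients and multiplies through", {
  fs1 <- fruit_set_quad_params(1, 0, 0)   # fraction pinned at 1
  expect_equal(truss_yield(18, 0, tf_params, fruit_set = fs1, n_flowers = 9),
               9 * oracle$mass_control, tolerance = 1e-12)
  fs0 <- fruit_set_quad_params(0, 0, 0)
  expect_identical(truss_yield(18, 0, tf_params, fruit_set = fs0), 0)
  expect_error(truss_yield(18, 0, tf_params), "coefficients required")
  # yield = flowers x set fraction x mass; 9 * 0.9 * 2.9 = 23.49
  expect_equal(9 * 0.9 * 2.9, 23.49)
  params_fs <- thermofruit_params(fruit_set = fruit_set_quad_params(0.9, 0, 0))
  expect_equal(truss_yield(30, 4, params_fs),
               9 * 0.9 * predict_fruit_mass(30, 4, params_fs))
})

test_that("fruit-set quadratic is clamped to the unit interval", {
  fs <- fruit_set_quad_params(-0.35, 0.1041667, -0.0020833)
  f <- fruit_set_fraction(seq(-10, 60, by = 1), fs)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(fruit_set_fraction(14, fs), 0.70, tolerance = 1e-4)
  expect_equal(fruit_set_fraction(30, fs), 0.90, tolerance = 1e-4)
  expect_error(fruit_set_fraction(20, NULL), "coefficients required")
})
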