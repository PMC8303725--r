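# Stejskal-Tanner decays, diffusion fitting and the fast-exchange
# two-state binding model.

test_that("Stejskal-Tanner intensity obeys the closed form and limits", {
  expect_equal(stejskal_tanner_intensity(1e-10, 3.5, 0, 2e-3, 0.2), 3.5)
  expect_equal(stejskal_tanner_intensity(0, 2, 0.4, 2e-3, 0.2), 2)
  # independent numeric evaluation of the exponent
  expect_equal(
    stejskal_tanner_intensity(1e-10, 1, 0.30, 2e-3, 0.2, gamma = 2.675e8),
    0.598, tolerance = 0.001 / 0.598)
  # monotone non-increasing in g and D
  g <- seq(0, 0.5, length.out = 20)
  I <- stejskal_tanner_intensity(1e-10, 1, g, 2e-3, 0.2)
  expect_true(all(diff(I) <= 0))
  expect_lt(stejskal_tanner_intensity(2e-10, 1, 0.3, 2e-3, 0.2),
            stejskal_tanner_intensity(1e-10, 1, 0.3, 2e-3, 0.2))
  expect_error(stejskal_tanner_intensity(1e-10, 1, 0.3, -1e-3, 0.2),
               "invalid parameter")
  expect_error(stejskal_tanner_intensity(1e-10, 1, 0.3, 2e-3, 1e-3),
               "delta must be")
})

test_that("log intensity is exactly linear in g^2", {
  g <- gradient_schedule()
  I <- stejskal_tanner_intensity(1.5e-10, 2, g, 2e-3, 0.18)
  fit <- lm(log(I) ~ I(g^2))
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1)
})

test_that("fit_diffusion recovers D exactly from noiseless decays", {
  for (D in c(1.13e-10, 3.07e-10, 5e-11)) {
    e <- gen_decay_dataset(D, I0 = 2.5)
    for (m in c("nls", "loglinear")) {
      est <- fit_diffusion(e, method = m)
      expect_equal(est$D, D, tolerance = 1e-6)
      expect_equal(est$I0, 2.5, tolerance = 1e-6)
      expect_equal(est$r_squared, 1, tolerance = 1e-9)
    }
  }
})

test_that("fit_diffusion stays within 5% under 1% multiplicative noise", {
  D <- 1.13e-10
  rel_err <- vapply(1:100, function(s) {
    e <- gen_decay_dataset(D, noise_frac = 0.01, seed = s)
    abs(fit_diffusion(e)$D - D) / D
  }, numeric(1))
  expect_lt(max(rel_err), 0.05)
  expect_lt(abs(mean(rel_err)), 0.05)  # no systematic bias
})

test_that("degenerate decay inputs are rejected", {
  g <- gradient_schedule()
  e <- decay_experiment("flat", g, rep(1, length(g)), 2e-3, 0.2)
  expect_error(fit_diffusion(e), "fit failure")
  expect_error(decay_experiment("x", c(1, 2, 3), c(1, 1, 1), 2e-3, 0.2),
               "at least 4")
  expect_error(decay_experiment("x", c(1, 2, 2, 3), rep(1, 4), 2e-3, 0.2),
               "strictly increasing")
  # rising intensities -> negative best-fit D
  expect_error(
    fit_diffusion(decay_experiment("up", g, seq(1, 2, length.out = 16),
                                   2e-3, 0.2)),
    "fit failure")
})

test_that("molar_fraction inverts the weighted-average law", {
  expect_equal(molar_fraction(1.47e-10, 3.07e-10, 1.13e-10),
               0.175, tolerance = 0.005)
  expect_equal(molar_fraction(3.07e-10, 3.07e-10, 1.13e-10), 1.0)
  expect_equal(molar_fraction(1.13e-10, 3.07e-10, 1.13e-10), 0.0)
  # strictly increasing in D_obs when D_free > D_complex
  d_obs <- seq(1.2e-10, 3e-10, length.out = 10)
  mfs <- vapply(d_obs, molar_fraction, numeric(1),
                D_free = 3.07e-10, D_complex = 1.13e-10)
  expect_true(all(diff(mfs) > 0))
  # clamping band and hard failure
  expect_warning(mf <- molar_fraction(1.11e-10, 2.11e-10, 1.13e-10),
                 "clamped")
  expect_equal(as.numeric(mf), 0)
  expect_error(molar_fraction(0.9e-10, 2.13e-10, 1.13e-10),
               "violates ordering")
  expect_error(molar_fraction(1e-10, 2e-10, 2e-10), "must differ")
})

test_that("complex_concentration is the bound-fraction mass balance", {
  expect_equal(complex_concentration(1, 4.5), 0)
  expect_equal(complex_concentration(0, 1.5), 1.5)
  expect_equal(complex_concentration(0.6404, 2.0), 0.7192)
  expect_error(complex_concentration(1.2, 1), "\\[0, 1\\]")
})

test_that("solve_equilibrium gives the physical quadratic root", {
  expect_equal(solve_equilibrium(0, 1, 2), 0)
  expect_equal(solve_equilibrium(2, 1, 2), (7 - sqrt(17)) / 4,
               tolerance = 1e-12)
  expect_equal(solve_equilibrium(1e6, 1, 2), 1, tolerance = 1e-3)
  for (Ka in c(0.1, 1, 50)) {
    x <- solve_equilibrium(Ka, 1.5, 4.5)
    expect_gte(x, 0); expect_lte(x, 1.5)
    expect_equal(Ka * (1.5 - x) * (4.5 - x), x, tolerance = 1e-9)
  }
})

test_that("binding_constant recovers the worked 1:1 example", {
  sys <- binding_system(1.0, 2.0, 3.0e-10, 1.0e-10,
                        2.2808e-10, 1.0e-10)
  res <- binding_constant(sys)
  expect_equal(res$Ka, 2.00, tolerance = 0.005)
  expect_equal(res$MF_ligand, 0.6404, tolerance = 1e-3)
  expect_equal(res$complex_conc, 0.7192, tolerance = 1e-3)
  # no binding limit
  res0 <- binding_constant(binding_system(1, 2, 3e-10, 1e-10,
                                          3e-10, 1e-10))
  expect_equal(res0$Ka, 0)
  expect_equal(res0$complex_conc, 0)
})

test_that("Ka round-trips through the forward equilibrium noiselessly", {
  D_free <- 3.07e-10; D_complex <- 1.13e-10
  for (Ka in c(0.1, 0.5, 2, 4.07, 20, 100)) {
    for (ratio in c(1, 2, 3)) {
      C_host <- 1.5; C_ligand <- ratio * C_host
      x <- solve_equilibrium(Ka, C_host, C_ligand)
      MF <- 1 - x / C_ligand
      D_obs <- MF * D_free + (1 - MF) * D_complex
      res <- binding_constant(
        binding_system(C_host, C_ligand, D_free, D_complex,
                       D_obs, D_complex))
      expect_equal(res$Ka, Ka, tolerance = 1e-6)
    }
  }
})

test_that("excess bound ligand triggers the stoichiometry warning", {
  # printed-style data: 3x ligand excess with 82% of ligand bound cannot
  # satisfy 1:1 stoichiometry
  res <- binding_constant(
    binding_system(1.5, 4.5, 3.07e-10, 1.13e-10, 1.47e-10, 1.13e-10))
  expect_true(is.na(res$Ka))
  expect_true(any(grepl("stoichiometry violation", res$warnings)))
  expect_equal(res$MF_ligand, 0.1753, tolerance = 1e-3)
  expect_equal(res$complex_conc, 3.711, tolerance = 1e-3)
})

test_that("binding_system validates ordering and positivity", {
  expect_error(binding_system(-1, 2, 3e-10, 1e-10, 2e-10, 1e-10),
               "positive")
  expect_error(binding_system(1, 2, 1e-10, 3e-10, 2e-10, 1e-10),
               "guest diffuses faster")
  expect_error(binding_system(1, 2, 3e-10, 1e-10, 5e-10, 1e-10),
               "must lie between")
})
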