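test_that("hazard matches the loglinear form by hand", {
  p <- aaa_growth_params()
  # b = (8.5, 0) at t = 0 gives m = 45 mm, m' = 2.05 mm/yr
  expect_equal(hazard(p, c(8.5, 0), 0),
               exp(-11.0 + 0.084 * 45 + 0.579 * 2.05), tolerance = 1e-12)
  # null association: hazard equals the baseline everywhere
  p0 <- null_assoc_params(log_h0 = -4)
  expect_equal(hazard(p0, c(5, 1), c(0, 2, 7)), rep(exp(-4), 3))
  # exponential link: adding da to alpha1 multiplies the hazard by exp(da*m)
  p1 <- jm_params(beta = p$beta, sigma_eps = p$sigma_eps, sigma0 = p$sigma0,
                  sigma1 = p$sigma1, rho = p$rho, baseline = p$baseline,
                  assoc = association("value_and_slope", c(2 * 0.084, 0.579)))
  m <- traj_value(p, c(0, 0), 3)
  expect_equal(hazard(p1, c(0, 0), 3) / hazard(p, c(0, 0), 3),
               exp(0.084 * m), tolerance = 1e-10)
})

test_that("cumulative hazard agrees with a dense trapezoid oracle", {
  p <- aaa_growth_params()
  s <- seq(0, 5, length.out = 1e5)
  h <- hazard(p, c(0, 0), s)
  H_oracle <- trapz(s, h)
  expect_equal(cum_hazard(p, c(0, 0), 0, 5), H_oracle, tolerance = 1e-6)
  expect_equal(cum_hazard(p, c(0, 0), 2, 2), 0)
  expect_error(cum_hazard(p, c(0, 0), 3, 1), "t0")
})

test_that("cumulative hazard is additive and constant-hazard exact", {
  p <- aaa_growth_params()
  set.seed(4)
  for (rep in 1:10) {
    b <- c(rnorm(1, 0, 6), rnorm(1, 0, 1.5))
    a <- runif(1, 0, 3); m <- a + runif(1, 0, 4); cc <- m + runif(1, 0, 4)
    expect_equal(cum_hazard(p, b, a, cc),
                 cum_hazard(p, b, a, m) + cum_hazard(p, b, m, cc),
                 tolerance = 1e-10)
  }
  p0 <- null_assoc_params(log_h0 = -2.2)
  expect_equal(cum_hazard(p0, c(1, 1), 1.5, 4), exp(-2.2) * 2.5,
               tolerance = 1e-12)
  expect_equal(survivor(p0, c(0, 0), 3), exp(-exp(-2.2) * 3),
               tolerance = 1e-12)
})

test_that("survivor is a proper nonincreasing survival curve", {
  set.seed(11)
  for (rep in 1:8) {
    p <- jm_params(beta = c(runif(1, 30, 45), runif(1, 0, 3), runif(1, 0, 0.15)),
                   sigma_eps = runif(1, 1, 4),
                   sigma0 = runif(1, 2, 8), sigma1 = runif(1, 0.5, 2.5),
                   rho = runif(1, -0.8, 0.8),
                   baseline = list(kind = "exponential",
                                   log_h0 = runif(1, -13, -7)),
                   assoc = association("value_and_slope",
                                       c(runif(1, 0, 0.15), runif(1, 0, 0.8))))
    b <- c(rnorm(1, 0, 3), rnorm(1, 0, 1))
    tt <- seq(0, 12, by = 1.5)
    S <- vapply(tt, function(u) survivor(p, b, u), numeric(1))
    expect_equal(S[1], 1)
    expect_true(all(S > 0 & S <= 1))
    expect_true(all(diff(S) <= 1e-12))
  }
})

test_that("weibull baseline follows the documented parameterisation", {
  p <- jm_params(beta = c(36.5, 2.05, 0.097), sigma_eps = 2.91,
                 sigma0 = 6.63, sigma1 = 1.79, rho = 0.567,
                 baseline = list(kind = "weibull", log_scale = -9,
                                 log_shape = log(1.4)),
                 assoc = association("value_and_slope", c(0, 0)))
  # h0(t) = exp(l) k t^(k-1); H0(t) = exp(l) t^k
  expect_equal(hazard(p, c(0, 0), 2), exp(-9) * 1.4 * 2^0.4, tolerance = 1e-12)
  # GL quadrature of the mildly singular t^(k-1) integrand: ~1e-4 relative
  expect_equal(cum_hazard(p, c(0, 0), 0, 3), exp(-9) * 3^1.4, tolerance = 1e-3)
})

test_that("survivor agrees with brute-force event-time simulation", {
  p <- aaa_growth_params()
  orc <- event_time_oracle(p, c(0, 0), horizon = 30, n_draws = 2e5, seed = 9)
  for (tt in c(2, 5, 10)) {
    S_hat <- orc$surv(tt)
    se <- sqrt(S_hat * (1 - S_hat) / 2e5)
    expect_lt(abs(survivor(p, c(0, 0), tt) - S_hat), 3 * se + 1e-4)
  }
})
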