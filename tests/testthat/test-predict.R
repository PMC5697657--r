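test_that("posterior b draws collapse to zero when Sigma is degenerate", {
  fit <- as_jm_fit(point_mass_params(), se = c(beta0 = 0))
  s <- subject_history("x", 65, times = c(0, 1), diameters = c(40, 42))
  d <- posterior_b_draws(fit, s, t = 1, n = 60, seed = 2,
                         theta_uncertainty = FALSE)
  expect_lt(max(abs(d$b)), 1e-3)
})

test_that("the posterior recovers a subject's random effects from rich data", {
  p <- aaa_growth_params()
  set.seed(5)
  b_true <- c(5, 0.8)
  tm <- seq(0, 8, length.out = 14)
  y <- traj_value(p, b_true, tm) + rnorm(length(tm), 0, 0.5)
  # low measurement noise so the data dominate the prior
  p_low <- jm_params(beta = p$beta, sigma_eps = 0.5, sigma0 = p$sigma0,
                     sigma1 = p$sigma1, rho = p$rho, baseline = p$baseline,
                     assoc = p$assoc)
  fit <- as_jm_fit(p_low, se = c(beta0 = 0))
  s <- subject_history("x", 65, tm, y)
  d <- posterior_b_draws(fit, s, t = 8, n = 800, seed = 6,
                         theta_uncertainty = FALSE)
  for (j in 1:2)
    expect_lt(abs(mean(d$b[, j]) - b_true[j]), 2.5 * sd(d$b[, j]))
  expect_gt(d$acceptance, 0.1)
  expect_lt(d$acceptance, 0.9)
})

test_that("draws fall back to the prior when no measurements precede t", {
  fit <- as_jm_fit(aaa_growth_params())
  s <- subject_history("x", 65, times = 2, diameters = 44, event_time = 3)
  expect_warning(posterior_b_draws(fit, s, t = 1, n = 20, seed = 1),
                 "survival alone")
})

test_that("conditional rupture probability obeys its boundary conditions", {
  fit <- as_jm_fit(aaa_growth_params())
  s <- subject_history("x", 65, 0, 45)
  r <- conditional_rupture_prob(fit, s, 0, seq(0, 8, 0.5), n_mc = 150,
                                seed = 3)
  expect_equal(r$mean_risk[1], 0)
  expect_true(all(diff(r$mean_risk) >= -1e-12))
  expect_true(all(r$mean_risk >= 0 & r$mean_risk <= 1))
  expect_true(all(r$lower <= r$mean_risk + 1e-12 &
                    r$mean_risk <= r$upper + 1e-12))
  expect_error(conditional_rupture_prob(fit, s, 2, numeric(0)), "non-empty")
  expect_error(conditional_rupture_prob(fit, s, 2, c(1, 3)), ">= t")
})

test_that("with no association the risk curve is the exponential closed form", {
  p0 <- null_assoc_params(log_h0 = -3)
  fit <- as_jm_fit(p0, se = c(beta0 = 0))
  s <- subject_history("x", 65, 0, 40)
  u <- seq(1, 6, 0.5)
  r <- conditional_rupture_prob(fit, s, 1, u, n_mc = 40, seed = 4,
                                theta_uncertainty = FALSE)
  expect_equal(r$mean_risk, 1 - exp(-exp(-3) * (u - 1)), tolerance = 1e-6)
  # no b dependence: bands collapse onto the mean
  expect_equal(r$lower, r$mean_risk, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r$upper, r$mean_risk, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("fixed-b conditional risk matches event-time simulation", {
  p <- point_mass_params()
  fit <- as_jm_fit(p, se = c(beta0 = 0))
  s <- subject_history("x", 65, 0, 36.5)
  t0 <- 2
  u <- c(4, 7, 10)
  r <- conditional_rupture_prob(fit, s, t0, u, n_mc = 50, seed = 7,
                                theta_uncertainty = FALSE)
  orc <- event_time_oracle(p, c(0, 0), horizon = 40, n_draws = 2e5, seed = 8)
  S_t <- orc$surv(t0)
  for (k in seq_along(u)) {
    F_hat <- 1 - orc$surv(u[k]) / S_t
    se <- sqrt(F_hat * (1 - F_hat) / (2e5 * S_t))
    expect_lt(abs(r$mean_risk[k] - F_hat), 3 * se + 1e-3)
  }
})

test_that("draw-wise conditioning is consistent across landmarks", {
  # 1 - F(u2|t) = (1 - F(u1|t)) (1 - F(u2|u1)) at a fixed b
  p <- aaa_growth_params()
  b <- c(4, 0.5)
  t0 <- 1; u1 <- 3; u2 <- 6
  F_ <- function(a, b2) 1 - exp(-cum_hazard(p, b, a, b2))
  expect_equal(1 - F_(t0, u2), (1 - F_(t0, u1)) * (1 - F_(u1, u2)),
               tolerance = 1e-12)
})

test_that("seeded prediction runs are bit-reproducible", {
  fit <- as_jm_fit(aaa_growth_params())
  s <- subject_history("x", 65, c(0, 1), c(42, 44))
  r1 <- conditional_rupture_prob(fit, s, 1, seq(1, 5, 0.5), n_mc = 80, seed = 11)
  r2 <- conditional_rupture_prob(fit, s, 1, seq(1, 5, 0.5), n_mc = 80, seed = 11)
  expect_identical(r1$F_draws, r2$F_draws)
  expect_identical(r1$mean_risk, r2$mean_risk)
})

test_that("predicted trajectories shrink towards the observed growth rate", {
  fit <- as_jm_fit(aaa_growth_params())
  slopes <- vapply(c(1, 4, 10), function(nm) {
    tm <- seq_len(nm) - 1
    di <- 45 - (nm - 1 - tm)          # 1 mm/year observed growth, ending 45
    s <- subject_history("x", 65 - (nm - 1), tm, di)
    pt <- predict_trajectory(fit, s, max(tm), max(tm) + c(0, 1), n_mc = 300,
                             seed = 12)
    mean(attr(pt, "slope_draws"))
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_gt(slopes[1], 2.5)  # single measurement: near the population rate
  expect_lt(slopes[3], 2.5)  # ten low-growth measurements pull it down
})

test_that("with no measurements the mean prediction is the population curve", {
  p <- aaa_growth_params()
  fit <- as_jm_fit(p, se = c(beta0 = 0))
  s <- subject_history("x", 65, numeric(0), numeric(0), event_time = 0)
  u <- c(0, 2, 5)
  pt <- suppressWarnings(predict_trajectory(fit, s, 0, u, n_mc = 4000,
                                            seed = 13,
                                            theta_uncertainty = FALSE))
  se_mc <- apply(attr(pt, "draws")$b, 2, sd) / sqrt(4000)
  expect_equal(pt$mean, traj_value(p, c(0, 0), u),
               tolerance = 3 * max(se_mc) * max(1 + u) + 0.02)
})
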