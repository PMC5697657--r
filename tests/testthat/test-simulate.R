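test_that("with null association the empirical event rate is the baseline", {
  # constant hazard, no deaths, no threshold in reach, long horizon
  p0 <- null_assoc_params(log_h0 = -4)
  des <- cohort_design(600, eligibility_mm = c(-1e6, 1e6),
                       threshold_mm = 1e7, fast_mm = 1e6, horizon = 50)
  co <- simulate_cohort(p0, des, lifetable = NULL, seed = 51)
  py <- sum(co$survival$obs_time_years)
  ev <- sum(co$survival$event)
  rate <- ev / py
  se <- sqrt(ev) / py
  expect_lt(abs(rate - exp(-4)), 3 * se)
})

test_that("noise-free, effect-free subjects lie exactly on the fixed curve", {
  p <- jm_params(beta = c(36.5, 2.05, 0.097), sigma_eps = 1e-12,
                 sigma0 = 1e-12, sigma1 = 1e-12, rho = 0,
                 baseline = list(kind = "exponential", log_h0 = -11),
                 assoc = association("value_and_slope", c(0.084, 0.579)))
  co <- simulate_cohort(p, cohort_design(20, eligibility_mm = c(30, 54)),
                        lifetable = NULL, seed = 52)
  expect_equal(co$longitudinal$diameter_mm,
               traj_value(p, c(0, 0), co$longitudinal$time_years),
               tolerance = 1e-8)
})

test_that("scan schedule switches from annual to 3-monthly at 45 mm", {
  co <- simulate_cohort(aaa_growth_params(), cohort_design(150),
                        gompertz_life_table(), seed = 53)
  long <- co$longitudinal
  for (id in unique(long$subject_id)) {
    rows <- long[long$subject_id == id, ]
    if (nrow(rows) < 2) next
    gaps <- diff(rows$time_years)
    expected <- ifelse(rows$diameter_mm[-nrow(rows)] < 45, 1, 0.25)
    expect_equal(gaps, expected, tolerance = 1e-9)
  }
})

test_that("follow-up ends at the first scan at or above 55 mm", {
  co <- simulate_cohort(aaa_growth_params(), cohort_design(200),
                        lifetable = NULL, seed = 54)
  long <- co$longitudinal
  sv <- co$survival
  for (i in seq_len(nrow(sv))) {
    rows <- long[long$subject_id == sv$subject_id[i], ]
    over <- which(rows$diameter_mm >= 55)
    if (length(over)) {
      expect_equal(over[1], nrow(rows))  # nothing recorded beyond it
      expect_equal(sv$obs_time_years[i], rows$time_years[over[1]])
      expect_equal(sv$event[i], 0L)
    }
  }
})

test_that("baseline measured diameters respect the eligibility window", {
  co <- simulate_cohort(aaa_growth_params(), cohort_design(200),
                        lifetable = NULL, seed = 55)
  base <- co$longitudinal[co$longitudinal$time_years == 0, "diameter_mm"]
  expect_true(all(base >= 30 & base <= 54))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  co1 <- simulate_cohort(aaa_growth_params(), cohort_design(40),
                         gompertz_life_table(), seed = 56)
  co2 <- simulate_cohort(aaa_growth_params(), cohort_design(40),
                         gompertz_life_table(), seed = 56)
  expect_identical(co1$longitudinal, co2$longitudinal)
  expect_identical(co1$survival, co2$survival)
})

test_that("a MASS-like cohort lands in the published event-rate ballpark", {
  co <- simulate_cohort(aaa_growth_params(), cohort_design(1122),
                        gompertz_life_table(), seed = 57)
  py <- sum(co$survival$obs_time_years)
  ev <- sum(co$survival$event)
  # ~33 ruptures in ~6085 person-years: demand the same order of magnitude
  expect_gt(py, 4000); expect_lt(py, 9000)
  expect_gt(ev, 10); expect_lt(ev, 80)
  fu <- mean(co$survival$obs_time_years)
  expect_gt(fu, 4); expect_lt(fu, 7)
})

test_that("the event-time oracle matches a constant-hazard closed form", {
  p0 <- null_assoc_params(log_h0 = -2)
  orc <- event_time_oracle(p0, c(0, 0), horizon = 30, n_draws = 4e4, seed = 58)
  for (tt in c(1, 3, 8)) {
    S <- exp(-exp(-2) * tt)
    se <- sqrt(S * (1 - S) / 4e4)
    expect_lt(abs(orc$surv(tt) - S), 3 * se + 1e-4)
  }
})

test_that("oracle precision tightens roughly as 1/sqrt(n)", {
  p0 <- null_assoc_params(log_h0 = -2)
  S <- exp(-exp(-2) * 3)
  err <- vapply(c(1e3, 16e3), function(n) {
    reps <- vapply(1:20, function(r)
      event_time_oracle(p0, c(0, 0), 30, n, seed = 600 + r)$surv(3),
      numeric(1))
    sd(reps)
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)  # 16x draws: ~4x tighter, allow slack
})
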