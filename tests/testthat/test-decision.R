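test_that("rupture case fatality composes pre-surgery and operative death", {
  expect_equal(rupture_case_fatality(operative_risk()), 0.55 + 0.45 * 0.37)
  expect_equal(rupture_case_fatality(
    operative_risk(q_surgery = 1, p_emergency = 0.37)), 0.37)
  expect_equal(rupture_case_fatality(operative_risk(q_surgery = 0)), 1)
})

test_that("elective mortality follows the age bands of Model 2", {
  r2 <- operative_risk(model = 2)
  expect_equal(p_elective(r2, c(60, 65.9, 66, 75.9, 76, 86, 100)),
               c(0.006, 0.006, 0.016, 0.016, 0.024, 0.030, 0.030))
  r1 <- operative_risk(model = 1)
  expect_equal(p_elective(r1, c(60, 80)), c(0.019, 0.019))
})

test_that("life-table survival pro-rates on the hazard scale", {
  lt <- life_table(60:70, rep(0.1, 11))
  expect_equal(s_nonaaa(lt, 60, 0), 1)
  expect_equal(s_nonaaa(lt, 60, 2), 0.81)
  expect_equal(s_nonaaa(lt, 60, 0.5), exp(0.5 * log(0.9)))
  expect_equal(s_nonaaa(lt, 63.25, 1), 0.9)   # fractional start, flat table
  # beyond the table: absorbing
  expect_lt(s_nonaaa(lt, 60, 20), 1e-10)
  expect_true(all(diff(s_nonaaa(lt, 62, seq(0, 8, 0.25))) <= 0))
  expect_error(life_table(c(60, 62), c(0.1, 0.1)), "contiguous")
})

test_that("the AAA survivor discounts rupture risk by its case fatality", {
  expect_equal(s_aaa(c(0, 0.5, 1), 0.7165), c(1, 1 - 0.5 * 0.7165, 0.2835))
  expect_equal(s_aaa(c(0.3, 0.9), 0), c(1, 1))
  expect_error(s_aaa(0.5, 1.2), "p_R")
})

test_that("decision limits: free surgery now, useless surgery never", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  s <- subject_history("x", 65, 0, 45)
  # costless intervention removes all rupture risk: operate immediately
  d0 <- optimal_intervention(fit, s, lt, operative_risk(model = 1, p_elective = 0),
                             t = 0, n_mc = 100, seed = 41,
                             theta_uncertainty = FALSE)
  expect_equal(d0$tx_opt, 0)
  expect_true(all(d0$tx_opt_draws == 0))
  # no rupture hazard: any operative risk makes "never operate" optimal
  fz <- as_jm_fit(null_assoc_params(log_h0 = -30), se = c(beta0 = 0))
  dz <- optimal_intervention(fz, s, lt, operative_risk(model = 2),
                             t = 0, n_mc = 40, seed = 42,
                             theta_uncertainty = FALSE)
  expect_equal(dz$tx_opt, max(dz$grid_tx))
})

test_that("with p_R = 0 and p_E = 0 life-years equal the life-table integral", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  s <- subject_history("x", 65, 0, 45)
  free <- operative_risk(model = 1, p_elective = 0, p_emergency = 0,
                         q_surgery = 1)
  d <- optimal_intervention(fit, s, lt, free, t = 0, n_mc = 40, seed = 43,
                            theta_uncertainty = FALSE)
  expect_lt(diff(range(d$expected_life_years)), 1e-9)
  u <- d$grid_tx
  expect_equal(d$expected_life_years[1], trapz(u, s_nonaaa(lt, 65, u)),
               tolerance = 1e-9)
})

test_that("under a flat non-AAA hazard life-years approach 1/lambda", {
  # q = 1 - exp(-0.2) gives hazard 0.2/yr; horizon truncation leaves
  # 1/lambda - integral tail exp(-lambda*T)/lambda
  q <- 1 - exp(-0.2)
  lt <- life_table(0:109, c(rep(q, 109), 1))
  fit <- as_jm_fit(aaa_growth_params())
  s <- subject_history("x", 65, 0, 45)
  free <- operative_risk(model = 1, p_elective = 0, p_emergency = 0,
                         q_surgery = 1)
  d <- optimal_intervention(fit, s, lt, free, t = 0, n_mc = 20, seed = 44,
                            theta_uncertainty = FALSE)
  horizon <- max(d$grid_tx)
  closed <- (1 - exp(-0.2 * horizon)) / 0.2
  expect_equal(d$expected_life_years[1], closed, tolerance = 1e-3)
})

test_that("the grid argmax dominates every candidate time, draw by draw", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  s <- subject_history("x", 65, 0, 50)
  d <- optimal_intervention(fit, s, lt, operative_risk(model = 2),
                            t = 0, n_mc = 120, seed = 45)
  best <- apply(d$ely_draws, 2, max)
  expect_true(all(d$ely_draws <= best[col(d$ely_draws)] + 1e-12))
  expect_true(d$tx_opt %in% d$grid_tx)
  # bounded by the non-AAA life expectancy
  u <- d$grid_tx
  expect_true(all(d$expected_life_years <= trapz(u, s_nonaaa(lt, 65, u)) + 1e-9))
})

test_that("optimal time decreases with baseline diameter", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  waits <- vapply(c(35, 45, 55, 65), function(diam) {
    s <- subject_history("x", 65, 0, diam)
    d <- optimal_intervention(fit, s, lt, operative_risk(model = 1),
                              t = 0, n_mc = 200, seed = 46)
    d$tx_opt
  }, numeric(1))
  expect_true(all(diff(waits) <= 0))
  expect_lt(waits[4], 1)  # 65 mm: operate almost immediately
})

test_that("age-banded elective mortality favours earlier surgery when young", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  s <- subject_history("x", 65, 0, 45)
  d1 <- optimal_intervention(fit, s, lt, operative_risk(model = 1),
                             t = 0, n_mc = 250, seed = 47)
  d2 <- optimal_intervention(fit, s, lt, operative_risk(model = 2),
                             t = 0, n_mc = 250, seed = 47)
  expect_lte(d2$tx_opt, d1$tx_opt)
  expect_lte(mean(d2$tx_opt_draws), mean(d1$tx_opt_draws))
})

test_that("halving the grid step barely moves the optimal value", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  s <- subject_history("x", 65, 0, 45)
  d1 <- optimal_intervention(fit, s, lt, operative_risk(model = 2), t = 0,
                             grid_step = 0.25, n_mc = 150, seed = 48)
  d2 <- optimal_intervention(fit, s, lt, operative_risk(model = 2), t = 0,
                             grid_step = 0.125, n_mc = 150, seed = 48)
  expect_lt(abs(d1$ely_at_opt - d2$ely_at_opt), 0.01)
})

test_that("the optimal policy weakly beats the fixed 55 mm threshold", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  s <- subject_history("x", 70, 0, 40)
  cmp <- compare_with_threshold_policy(fit, s, lt, operative_risk(model = 2),
                                       t = 0, n_mc = 200, seed = 49)
  expect_gte(cmp$difference, 0)
  expect_gte(cmp$pct_gain, 0)
  expect_true(all(cmp$tx_threshold_draws >= 0))
})

test_that("life-year gains from personalised timing shrink with age", {
  fit <- as_jm_fit(aaa_growth_params())
  lt <- gompertz_life_table()
  diffs <- vapply(c(65, 80), function(age) {
    s <- subject_history("x", age, 0, 35)
    compare_with_threshold_policy(fit, s, lt, operative_risk(model = 2),
                                  t = 0, n_mc = 300, seed = 50)$difference
  }, numeric(1))
  expect_gt(diffs[1], diffs[2])
})
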