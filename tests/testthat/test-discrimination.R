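# a cohort small enough for exhaustive pair counting, with known outcomes
pair_cohort <- function() {
  long <- data.frame(
    subject_id = rep(sprintf("p%d", 1:6), each = 2),
    time_years = rep(c(0, 1), 6),
    diameter_mm = c(34, 35, 40, 43, 46, 50, 36, 37, 44, 48, 38, 40))
  surv <- data.frame(
    subject_id = sprintf("p%d", 1:6),
    baseline_age_years = rep(67, 6),
    obs_time_years = c(6, 2.4, 1.9, 5.5, 2.8, 4.2),
    event = c(0L, 1L, 1L, 0L, 0L, 0L))
  aaa_cohort(long, surv)
}

test_that("dynamic AUC equals an exhaustive pair count on small data", {
  fit <- as_jm_fit(aaa_growth_params())
  co <- pair_cohort()
  t <- 1; dt <- 2
  a <- dynamic_auc(fit, co, t, dt)
  # oracle: recompute risks independently via the survivor ratio at the
  # conditional mode, then count all case/control pairs by hand
  sv <- co$survival
  case <- which(sv$event == 1 & sv$obs_time_years > t &
                  sv$obs_time_years <= t + dt)
  ctrl <- which(sv$obs_time_years > t + dt)
  risk <- vapply(seq_len(nrow(sv)), function(i) {
    s <- co$subjects[[i]]
    d <- posterior_b_draws(fit, s, t, n = 1, seed = 1,
                           theta_uncertainty = FALSE)
    b <- d$mode
    1 - survivor(fit$params, b, t + dt) / survivor(fit$params, b, t)
  }, numeric(1))
  num <- 0; den <- 0
  for (i in case) for (j in ctrl) {
    num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    den <- den + 1
  }
  expect_equal(as.numeric(a), num / den, tolerance = 1e-10)
  expect_equal(attr(a, "n_cases"), length(case))
  expect_equal(attr(a, "n_controls"), length(ctrl))
})

test_that("identical predictions give AUC 1/2 and a perfect ranking gives 1", {
  co <- pair_cohort()
  # all-tie predictions: a model with no association ranks nobody
  fit0 <- as_jm_fit(null_assoc_params(log_h0 = -4), se = c(beta0 = 0))
  expect_equal(as.numeric(dynamic_auc(fit0, co, 1, 2)), 0.5)
  # perfect separation: cases carry much larger diameters
  long <- co$longitudinal
  sv <- co$survival
  isev <- sv$subject_id[sv$event == 1]
  long$diameter_mm <- ifelse(long$subject_id %in% isev,
                             long$diameter_mm + 40, long$diameter_mm)
  co2 <- aaa_cohort(long, sv)
  fit <- as_jm_fit(aaa_growth_params())
  expect_equal(as.numeric(dynamic_auc(fit, co2, 1, 2)), 1)
})

test_that("AUC is undefined (with a warning) without comparable pairs", {
  co <- pair_cohort()
  fit <- as_jm_fit(aaa_growth_params())
  expect_warning(a <- dynamic_auc(fit, co, 5.9, 2), "comparable")
  expect_true(is.na(a))
})

test_that("AUC is invariant to monotone transforms of the risk scale", {
  # ranking by F(t+dt|t) equals ranking by the cumulative hazard increment
  fit <- as_jm_fit(aaa_growth_params())
  co <- pair_cohort()
  a1 <- dynamic_auc(fit, co, 1, 2)
  risk <- vapply(co$subjects, function(s) {
    d <- posterior_b_draws(fit, s, 1, n = 1, seed = 1,
                           theta_uncertainty = FALSE)
    cum_hazard(fit$params, d$mode, 1, 3)       # -log(1 - F): monotone in F
  }, numeric(1))
  sv <- co$survival
  case <- which(sv$event == 1 & sv$obs_time_years > 1 & sv$obs_time_years <= 3)
  ctrl <- which(sv$obs_time_years > 3)
  cmp <- outer(risk[case], risk[ctrl], function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(as.numeric(a1), mean(cmp), tolerance = 1e-10)
})

test_that("the DDI is an events-weighted average of landmark AUCs", {
  fit <- as_jm_fit(aaa_growth_params())
  co <- simulate_cohort(aaa_growth_params(), cohort_design(250),
                        lifetable = NULL, seed = 61)
  d <- suppressWarnings(ddi(fit, co, dt = 2, landmarks = c(1, 2, 3)))
  ok <- is.finite(d$auc) & d$events > 0
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_equal(d$summary, sum(d$weights[ok] * d$auc[ok]), tolerance = 1e-12)
  expect_true(all(d$auc[ok] >= 0 & d$auc[ok] <= 1))
  # single landmark: the DDI is that AUC
  d1 <- suppressWarnings(ddi(fit, co, dt = 2, landmarks = 1))
  a1 <- dynamic_auc(fit, co, 1, 2)
  expect_equal(d1$summary, as.numeric(a1), tolerance = 1e-12)
})
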