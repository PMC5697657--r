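# Shared fixtures and independent oracles, all built in code.

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# deterministic 3-subject cohort for likelihood checks
tiny_cohort <- function() {
  long <- data.frame(
    subject_id = rep(c("a", "b", "c"), c(3, 2, 4)),
    time_years = c(0, 1, 2, 0, 1, 0, 1, 2, 3),
    diameter_mm = c(35, 38, 40, 44, 46, 31, 33, 36, 37))
  surv <- data.frame(
    subject_id = c("a", "b", "c"),
    baseline_age_years = c(65, 70, 68),
    obs_time_years = c(2.5, 1.8, 3.2),
    event = c(0L, 1L, 0L))
  aaa_cohort(long, surv)
}

# plain Monte-Carlo integration of one subject's likelihood contribution
# (prior draws of b; independent of the adaptive quadrature path)
mc_loglik_subject <- function(params, subj, n = 5e4, seed = 1) {
  set.seed(seed)
  L <- t(chol(params$Sigma))
  q <- params$spec$q
  B <- L %*% matrix(rnorm(q * n), q)
  vals <- vapply(seq_len(n), function(k) {
    b <- B[, k]
    m <- traj_value(params, b, subj$times)
    lp <- sum(dnorm(subj$diameters, m, params$sigma_eps, log = TRUE)) -
      cum_hazard(params, b, 0, subj$event_time)
    if (subj$event == 1) lp <- lp + log(hazard(params, b, subj$event_time))
    lp
  }, numeric(1))
  mx <- max(vals)
  w <- exp(vals - mx)
  list(est = mx + log(mean(w)), se = sd(w) / sqrt(n) / mean(w))
}

# parameter set with the association switched off and a chosen constant
# baseline hazard (closed-form survival)
null_assoc_params <- function(log_h0 = -3) {
  jm_params(beta = c(36.5, 2.05, 0.097), sigma_eps = 2.91,
            sigma0 = 6.63, sigma1 = 1.79, rho = 0.567,
            baseline = list(kind = "exponential", log_h0 = log_h0),
            assoc = association("value_and_slope", c(0, 0)))
}

# near-degenerate random effects: posterior for b is a point mass at 0
point_mass_params <- function(base = aaa_growth_params()) {
  jm_params(beta = base$beta, sigma_eps = base$sigma_eps,
            sigma0 = 1e-4, sigma1 = 1e-4, rho = 0,
            baseline = base$baseline, assoc = base$assoc)
}
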