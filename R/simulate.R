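# Synthetic screening cohorts generated from the joint model, emulating a
# surveillance programme: baseline eligibility on the measured diameter,
# scan intervals driven by the latest measurement, censoring at the first
# scan at or above the surgical threshold, rupture times drawn from the
# subject's own hazard, and non-AAA deaths from a life table.

#' Screening cohort design
#'
#' @param n_subjects Number of subjects (default 1122, a large-screening-
#'   programme scale).
#' @param age_range Baseline age range, uniform (default 65-74).
#' @param eligibility_mm Baseline measured-diameter eligibility window
#'   (default 30-54 mm).
#' @param fast_mm Diameter from which scans switch from annual to 3-monthly
#'   (default 45 mm).
#' @param threshold_mm Surgical referral threshold: follow-up is censored at
#'   the first scan at or above it (default 55 mm).
#' @param slow_gap,fast_gap Scan intervals in years below/at-or-above
#'   `fast_mm` (defaults 1 and 0.25).
#' @param horizon Administrative censoring time in years (default 15).
#' @return An object of class `aaa_cohort_design`.
#' @export
cohort_design <- function(n_subjects = 1122, age_range = c(65, 74),
                          eligibility_mm = c(30, 54), fast_mm = 45,
                          threshold_mm = 55, slow_gap = 1, fast_gap = 0.25,
                          horizon = 15) {
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            length(eligibility_mm) == 2,
            eligibility_mm[1] < fast_mm, fast_mm < threshold_mm,
            slow_gap > 0, fast_gap > 0, horizon > 0)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 eligibility_mm = eligibility_mm, fast_mm = fast_mm,
                 threshold_mm = threshold_mm, slow_gap = slow_gap,
                 fast_gap = fast_gap, horizon = horizon),
            class = "aaa_cohort_design")
}

# rupture time for a fixed b: solve H(0, T) = e by bracketing + uniroot
.draw_rupture_time <- function(params, b, e, cap = 1e4, gl = 15) {
  hi <- 1
  H <- cum_hazard(params, b, 0, hi, gl = gl)
  while (H < e && hi < cap) {
    hi <- hi * 2
    H <- cum_hazard(params, b, 0, hi, gl = gl)
  }
  if (H < e) return(Inf)  # hazard too low to reach e within the cap
  stats::uniroot(function(tt) cum_hazard(params, b, 0, tt, gl = gl) - e,
                 interval = c(0, hi), tol = 1e-6)$root
}

#' Simulate a synthetic surveillance cohort
#'
#' Per subject: draws random effects, redraws until the *measured* baseline
#' diameter falls inside the eligibility window (screening detects by
#' measurement, not by the latent size), schedules scans by the latest
#' measurement (annual below `fast_mm`, 3-monthly at or above), draws the
#' rupture time by inverting the subject's cumulative hazard, draws a
#' non-AAA death time from the life table, and records the first of
#' rupture, non-AAA death, threshold censoring, and administrative
#' censoring. Seeded and bit-reproducible.
#'
#' @param params Generating [jm_params()] (default [aaa_growth_params()]).
#' @param design An [cohort_design()].
#' @param lifetable Optional [life_table()] for non-AAA deaths; `NULL`
#'   disables non-AAA mortality.
#' @param seed Optional RNG seed.
#' @return An [aaa_cohort()] with an extra element `truth`: per-subject
#'   random effects and latent event times.
#' @export
simulate_cohort <- function(params = aaa_growth_params(),
                            design = cohort_design(), lifetable = NULL,
                            seed = NULL) {
  stopifnot(inherits(params, "aaa_jm_params"),
            inherits(design, "aaa_cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  q <- params$spec$q
  Lc <- t(chol(params$Sigma))
  n <- design$n_subjects
  long_id <- list(); long_t <- list(); long_y <- list()
  surv <- data.frame(subject_id = character(n), baseline_age_years = NA_real_,
                     obs_time_years = NA_real_, event = NA_integer_,
                     stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = character(n), b0 = NA_real_, b1 = NA_real_,
                      rupture_time = NA_real_, death_time = NA_real_,
                      stringsAsFactors = FALSE)
  elig <- design$eligibility_mm
  for (i in seq_len(n)) {
    id <- sprintf("s%04d", i)
    age <- stats::runif(1, design$age_range[1], design$age_range[2])
    repeat {
      b <- drop(Lc %*% stats::rnorm(q))
      y0 <- traj_value(params, b, 0) + stats::rnorm(1, 0, params$sigma_eps)
      if (y0 >= elig[1] && y0 <= elig[2]) break
    }
    t_r <- .draw_rupture_time(params, b, stats::rexp(1))
    t_d <- if (is.null(lifetable)) Inf
           else .lt_death_time(lifetable, age, stats::rexp(1))
    t_end <- min(t_r, t_d, design$horizon)

    times <- 0
    ys <- y0
    t_c <- Inf
    repeat {
      last_y <- ys[length(ys)]
      if (last_y >= design$threshold_mm) {  # referral: censor at this scan
        t_c <- times[length(times)]
        break
      }
      gap <- if (last_y < design$fast_mm) design$slow_gap else design$fast_gap
      t_next <- times[length(times)] + gap
      if (t_next >= t_end) break
      times <- c(times, t_next)
      ys <- c(ys, traj_value(params, b, t_next) +
                   stats::rnorm(1, 0, params$sigma_eps))
    }
    T_obs <- min(t_end, t_c)
    delta <- as.integer(is.finite(t_r) && t_r <= T_obs)
    keep <- times <= T_obs
    long_id[[i]] <- rep(id, sum(keep))
    long_t[[i]] <- times[keep]
    long_y[[i]] <- ys[keep]
    surv[i, ] <- list(id, age, T_obs, delta)
    truth[i, ] <- list(id, b[1], if (q == 2) b[2] else NA_real_, t_r, t_d)
  }
  cohort <- aaa_cohort(
    data.frame(subject_id = unlist(long_id), time_years = unlist(long_t),
               diameter_mm = unlist(long_y), stringsAsFactors = FALSE),
    surv)
  cohort$truth <- truth
  cohort$design <- design
  cohort$seed <- seed
  cohort
}

#' Brute-force event-time oracle for a fixed random-effect vector
#'
#' Simulates rupture times by inverse-CDF sampling on a dense time grid
#' (cumulative hazard by trapezoidal integration of the hazard itself,
#' independent of the quadrature used elsewhere) and returns the empirical
#' survivor curve. A validation tool for [survivor()] and
#' [conditional_rupture_prob()].
#'
#' @inheritParams traj_value
#' @param horizon Maximum simulated time (years).
#' @param n_draws Number of simulated event times.
#' @param seed Optional RNG seed.
#' @param grid_n Density of the inversion grid (default 4000 points).
#' @return A list with `times` (draws, `Inf` when beyond the horizon) and
#'   `surv(t)`, the empirical survivor function.
#' @export
event_time_oracle <- function(params, b, horizon = 30, n_draws = 1e5,
                              seed = NULL, grid_n = 4000) {
  if (!is.null(seed)) set.seed(seed)
  b <- .check_b(params, b)
  grid <- seq(0, horizon, length.out = grid_n)
  h <- hazard(params, b, grid)
  H <- .cumtrapz(grid, h)
  e <- stats::rexp(n_draws)
  times <- rep(Inf, n_draws)
  inside <- e <= H[grid_n]
  times[inside] <- stats::approx(H, grid, xout = e[inside], ties = "ordered")$y
  list(times = times, horizon = horizon,
       surv = function(t) vapply(t, function(tt) mean(times > tt), numeric(1)))
}
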