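# Expected-life-years decision model. Before an elective repair at time
# Tx the patient is exposed to both rupture-related death (conditional
# rupture probability times rupture case fatality) and non-AAA mortality
# from a life table; after a successful repair only non-AAA mortality
# remains. Expected remaining life-years as a function of Tx are maximised
# over a 3-month grid.

#' Life table of annual non-AAA death probabilities
#'
#' @param ages Integer ages (contiguous).
#' @param q Annual death probability at each age, in `[0, 1]`; the terminal
#'   age may have `q = 1` (absorbing).
#' @return An object of class `aaa_life_table`.
#' @export
life_table <- function(ages, q) {
  ages <- as.integer(ages)
  if (length(ages) != length(q)) stop("ages and q must have equal length")
  if (any(diff(ages) != 1L)) stop("ages must be contiguous")
  if (any(q < 0 | q > 1)) stop("q must be in [0, 1]")
  # annual hazards; q = 1 becomes a numerically absorbing state
  lam <- -log(pmax(1 - q, 1e-300))
  structure(list(ages = ages, q = as.numeric(q), lambda = lam),
            class = "aaa_life_table")
}

#' Synthetic Gompertz life table
#'
#' A smooth stand-in for a national (e.g. ONS-style) male life table:
#' annual hazard `a * exp(b * (x + 0.5))` at age `x`. The defaults give a
#' remaining life expectancy at age 65 of roughly 16 years, in line with UK
#' males of the early 2000s. Synthetic: use a real national table for any
#' substantive analysis.
#'
#' @param ages Integer ages covered (default 0:109).
#' @param a,b Gompertz level and log-linear slope of the annual hazard.
#' @return An [life_table()] object.
#' @export
gompertz_life_table <- function(ages = 0:109, a = 3.5e-5, b = 0.095) {
  lam <- a * exp(b * (ages + 0.5))
  q <- 1 - exp(-lam)
  q[length(q)] <- 1
  life_table(ages, q)
}

# cumulative non-AAA hazard from the table start to (possibly fractional)
# age; piecewise linear on the hazard scale, absorbing beyond the table
.lt_cumhaz <- function(table, age) {
  a0 <- table$ages[1]
  aend <- table$ages[length(table$ages)] + 1
  cum <- c(0, cumsum(table$lambda))
  vapply(age, function(a) {
    if (a <= a0) return(0)
    if (a >= aend) return(cum[length(cum)] + (a - aend) * 700)
    i <- floor(a - a0)
    cum[i + 1] + (a - a0 - i) * table$lambda[i + 1]
  }, numeric(1))
}

#' Non-AAA survival from a life table
#'
#' Probability of surviving non-AAA causes from `current_age` to
#' `current_age + u`, under a piecewise-constant annual hazard
#' `-log(1 - q_x)` with fractional years pro-rated on the hazard scale.
#' Ages beyond the table are treated as absorbing (survival 0).
#'
#' @param table An [life_table()].
#' @param current_age Age in years (may be fractional).
#' @param u Years ahead (vectorised, >= 0).
#' @return Survival probabilities in `[0, 1]`.
#' @export
#' @examples
#' lt <- life_table(60:70, rep(0.1, 11))
#' s_nonaaa(lt, 60, 2)   # (1 - 0.1)^2
s_nonaaa <- function(table, current_age, u) {
  stopifnot(inherits(table, "aaa_life_table"), all(u >= 0))
  exp(-( .lt_cumhaz(table, current_age + u) - .lt_cumhaz(table, current_age)))
}

# inverse of the life-table cumulative hazard: years until non-AAA death
# for a standard-exponential draw e, from current_age
.lt_death_time <- function(table, current_age, e) {
  target <- .lt_cumhaz(table, current_age) + e
  aend <- table$ages[length(table$ages)] + 1
  cum <- c(0, cumsum(table$lambda))
  if (target >= cum[length(cum)]) return(aend - current_age)  # absorbed
  i <- findInterval(target, cum, left.open = FALSE)
  age_at <- table$ages[1] + (i - 1) + (target - cum[i]) / table$lambda[i]
  max(age_at - current_age, 0)
}

#' Operative risk model
#'
#' Peri-operative mortality inputs for the decision model. Model 1 uses a
#' constant elective mortality; Model 2 makes elective mortality age-banded
#' (mortality rises with age at operation). Emergency repair after rupture
#' is described by the proportion of ruptures reaching surgery and the
#' emergency operative mortality.
#'
#' @param model 1 (constant elective mortality) or 2 (age-banded).
#' @param p_elective Constant elective mortality (Model 1; default 0.019).
#' @param bands Age-band thresholds for Model 2 (lower edges).
#' @param band_p Elective mortality within each band (Model 2 defaults
#'   0.006 / 0.016 / 0.024 / 0.030 for <66, 66-75, 76-85, 86+).
#' @param p_emergency Emergency operative mortality (default 0.37).
#' @param q_surgery Proportion of ruptures reaching emergency surgery
#'   (default 0.45).
#' @return An object of class `aaa_operative_risk`.
#' @export
operative_risk <- function(model = 2, p_elective = 0.019,
                           bands = c(0, 66, 76, 86),
                           band_p = c(0.006, 0.016, 0.024, 0.030),
                           p_emergency = 0.37, q_surgery = 0.45) {
  stopifnot(model %in% c(1, 2), length(bands) == length(band_p),
            all(band_p >= 0 & band_p <= 1),
            p_elective >= 0, p_elective <= 1,
            p_emergency >= 0, p_emergency <= 1,
            q_surgery >= 0, q_surgery <= 1)
  structure(list(model = model, p_elective = p_elective, bands = bands,
                 band_p = band_p, p_emergency = p_emergency,
                 q_surgery = q_surgery),
            class = "aaa_operative_risk")
}

#' Elective operative mortality at a given age
#'
#' @param risk An [operative_risk()].
#' @param age Age at operation, years (vectorised).
#' @return Mortality probability per operation.
#' @export
p_elective <- function(risk, age) {
  if (risk$model == 1) rep(risk$p_elective, length(age))
  else risk$band_p[findInterval(age, risk$bands)]
}

#' Short-term case fatality of rupture
#'
#' Combines death before emergency surgery with emergency operative
#' mortality: `p_R = (1 - q_s) + q_s * p_em`.
#'
#' @param risk An [operative_risk()].
#' @return Probability of death given rupture.
#' @export
#' @examples
#' rupture_case_fatality(operative_risk())  # 0.55 + 0.45 * 0.37 = 0.7165
rupture_case_fatality <- function(risk) {
  (1 - risk$q_surgery) + risk$q_surgery * risk$p_emergency
}

#' AAA-related survivor-like function
#'
#' `S_AAA(u | t) = 1 - F(u | t) * p_R`: survival of AAA-related death,
#' obtained by discounting the conditional rupture probability by the
#' rupture case fatality.
#'
#' @param F_risk Conditional rupture probabilities (vector or matrix).
#' @param p_R Rupture case fatality in `[0, 1]`.
#' @return Values in `[1 - p_R, 1]`, same shape as `F_risk`.
#' @export
s_aaa <- function(F_risk, p_R) {
  stopifnot(p_R >= 0, p_R <= 1)
  1 - F_risk * p_R
}

# trapezoid weights for a (possibly non-uniform) grid
.trap_w <- function(grid) {
  n <- length(grid)
  if (n == 1) return(0)
  d <- diff(grid)
  c(d[1], d[-1] + d[-(n - 1)], d[n - 1]) / 2
}

.cumtrapz <- function(grid, y) {
  n <- length(grid)
  if (is.matrix(y)) {
    seg <- diff(grid) * (y[-n, , drop = FALSE] + y[-1, , drop = FALSE]) / 2
    rbind(0, apply(seg, 2, cumsum))
  } else {
    c(0, cumsum(diff(grid) * (y[-n] + y[-1]) / 2))
  }
}

# Shared engine: per-draw expected life-years over the intervention grid.
# Returns the grid, the n_grid x n_mc ELY matrix, per-draw latent
# trajectories, and the ingredients (S_na, F draws, p_E at grid ages).
.decision_engine <- function(fit, subject, lifetable, risk, t,
                             grid_step = 0.25, horizon_age = 105,
                             n_mc = 1000, seed = NULL,
                             ely_variant = c("literal", "aaa_weighted"),
                             gl = 7, theta_uncertainty = TRUE, draws = NULL) {
  ely_variant <- match.arg(ely_variant)
  age_t <- subject$baseline_age + t
  if (age_t >= horizon_age) stop("subject already at or beyond the horizon age")
  u_max <- t + (horizon_age - age_t)
  grid <- seq(t, u_max, by = grid_step)
  if (grid[length(grid)] < u_max) grid <- c(grid, u_max)

  rc <- conditional_rupture_prob(fit, subject, t, grid, n_mc = n_mc,
                                 seed = seed, gl = gl,
                                 theta_uncertainty = theta_uncertainty,
                                 draws = draws)
  FD <- rc$F_draws                       # n_grid x n_mc
  n_mc <- ncol(FD)
  p_R <- rupture_case_fatality(risk)
  S_aaa_d <- s_aaa(FD, p_R)
  S_na <- s_nonaaa(lifetable, age_t, grid - t)
  pE <- p_elective(risk, age_t + (grid - t))

  pre <- .cumtrapz(grid, S_na * S_aaa_d)             # n_grid x n_mc
  cum_na <- .cumtrapz(grid, S_na)
  tail_na <- cum_na[length(grid)] - cum_na           # n_grid
  post <- if (ely_variant == "literal")
    matrix((1 - pE) * tail_na, length(grid), n_mc)
  else
    ((1 - pE) * tail_na) * S_aaa_d
  ELY <- pre + post

  M <- matrix(NA_real_, length(grid), n_mc)          # latent trajectories
  for (k in seq_len(n_mc))
    M[, k] <- traj_value(rc$draws$params[[k]], rc$draws$b[k, ], grid)

  list(grid = grid, ELY = ELY, M = M, risk_curve = rc, S_na = S_na,
       pE = pE, p_R = p_R, age_t = age_t, variant = ely_variant)
}

#' Expected remaining life-years for a given intervention time
#'
#' Trapezoidal-rule evaluation of expected remaining life-years given an
#' elective repair at `tx`: the area under the overall (non-AAA times
#' AAA-related) survivor curve up to `tx`, plus the non-AAA survival tail
#' after `tx` discounted by the elective operative mortality at the age
#' reached at `tx`. Averaged across the Monte-Carlo draws.
#'
#' @inheritParams optimal_intervention
#' @param tx Candidate intervention time (years since entry, `>= t`);
#'   vectorised.
#' @return Expected life-years for each `tx`.
#' @export
expected_life_years <- function(fit, subject, lifetable, risk, t, tx,
                                grid_step = 0.25, horizon_age = 105,
                                n_mc = 1000, seed = NULL,
                                ely_variant = "literal", gl = 7,
                                theta_uncertainty = TRUE) {
  if (any(tx < t)) stop("tx must be >= t")
  eng <- .decision_engine(fit, subject, lifetable, risk, t, grid_step,
                          horizon_age, n_mc, seed, ely_variant, gl,
                          theta_uncertainty)
  mean_curve <- rowMeans(eng$ELY)
  stats::approx(eng$grid, mean_curve, xout = pmin(tx, max(eng$grid)),
                rule = 2)$y
}

#' Optimal time of elective intervention
#'
#' Maximises expected remaining life-years over a grid of candidate
#' intervention times (3-month spacing by default, up to the horizon age).
#' The per-draw argmax gives a Monte-Carlo distribution for the optimal
#' time; the point estimate is the argmax of the draw-averaged curve. Ties
#' are broken to the earliest time. The diameter at the optimum is obtained
#' by substituting the optimal time back into the growth model.
#'
#' @inheritParams posterior_b_draws
#' @param lifetable An [life_table()] for non-AAA mortality.
#' @param risk An [operative_risk()].
#' @param t Conditioning time (years since entry); defaults to the
#'   subject's last measurement time.
#' @param grid_step Grid spacing in years (default 0.25, i.e. 3-monthly).
#' @param horizon_age Horizon age in years (default 105); reaching it is
#'   encoded as "never operate" (the post-operative term vanishes there).
#' @param n_mc Monte-Carlo iterations (default 1000).
#' @param ely_variant `"literal"` uses the plain post-intervention term
#'   `(1 - p_E) * integral of S_nonAAA`; `"aaa_weighted"` additionally
#'   weights it by the probability of being AAA-death-free at `tx`.
#' @param gl Gauss-Legendre order per grid segment.
#' @param level Coverage of the percentile interval for the optimal time.
#' @param draws Optional precomputed [posterior_b_draws()].
#' @return An object of class `aaa_decision`: grid, mean expected
#'   life-years curve, `tx_opt`, draws of the optimal time, percentile
#'   interval, coefficient of variation (of the waiting time `tx_opt - t`),
#'   and the diameter at the optimum (`diameter_at_opt`: the median across
#'   draws of the latent diameter at that draw's own optimal time — the
#'   median is used because never-operate draws extrapolate the growth
#'   curve far beyond the data and skew the mean; the full distribution is
#'   in `diameter_draws`).
#' @export
optimal_intervention <- function(fit, subject, lifetable, risk,
                                 t = NULL, grid_step = 0.25,
                                 horizon_age = 105, n_mc = 1000,
                                 seed = NULL, ely_variant = "literal",
                                 gl = 7, level = 0.95,
                                 theta_uncertainty = TRUE, draws = NULL) {
  if (is.null(t)) t <- if (length(subject$times)) max(subject$times) else 0
  eng <- .decision_engine(fit, subject, lifetable, risk, t, grid_step,
                          horizon_age, n_mc, seed, ely_variant, gl,
                          theta_uncertainty, draws)
  grid <- eng$grid
  opt_idx <- apply(eng$ELY, 2, which.max)      # earliest tie by which.max
  tx_draws <- grid[opt_idx]
  ely_mean <- rowMeans(eng$ELY)
  idx_pt <- which.max(ely_mean)
  tx_opt <- grid[idx_pt]
  diam_draws <- eng$M[cbind(opt_idx, seq_along(opt_idx))]
  wait <- tx_draws - t
  a <- (1 - level) / 2
  structure(list(grid_tx = grid, expected_life_years = ely_mean,
                 ely_draws = eng$ELY,
                 tx_opt = tx_opt, tx_opt_draws = tx_draws,
                 interval = stats::quantile(tx_draws, c(a, 1 - a)),
                 cv = if (mean(wait) > 0) stats::sd(wait) / mean(wait)
                      else NA_real_,
                 diameter_at_opt = stats::median(diam_draws),
                 diameter_draws = diam_draws,
                 ely_at_opt = ely_mean[idx_pt],
                 t = t, age_t = eng$age_t, p_R = eng$p_R,
                 variant = eng$variant, n_mc = ncol(eng$ELY), seed = seed,
                 risk_curve = eng$risk_curve),
            class = "aaa_decision")
}

#' @export
print.aaa_decision <- function(x, ...) {
  cat(sprintf("Optimal elective intervention for subject aged %.1f at t = %.2f y\n",
              x$age_t, x$t))
  cat(sprintf("  tx_opt = %.2f y (wait %.2f y); percentile interval [%.2f, %.2f]; CV = %.2f\n",
              x$tx_opt, x$tx_opt - x$t, x$interval[1], x$interval[2], x$cv))
  cat(sprintf("  expected life-years at optimum: %.3f\n", x$ely_at_opt))
  cat(sprintf("  diameter at optimum: %.1f mm (%s variant, %d MC draws)\n",
              x$diameter_at_opt, x$variant, x$n_mc))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare the optimal policy with a fixed diameter threshold
#'
#' For each Monte-Carlo draw, the threshold policy operates at the first
#' grid time at which the draw's latent trajectory reaches `threshold_mm`
#' (immediately if already there; never within the horizon if it never
#' crosses), while the optimal policy operates at that draw's expected
#' life-years argmax. Returns the expected life-years under both policies
#' and their difference, which is nonnegative by construction up to grid
#' resolution.
#'
#' @inheritParams optimal_intervention
#' @param threshold_mm Intervention threshold diameter (default 55 mm).
#' @return A list with `ely_opt`, `ely_threshold`, `difference`,
#'   `pct_gain` (percentage of remaining life-years gained), and the
#'   per-draw threshold crossing times.
#' @export
compare_with_threshold_policy <- function(fit, subject, lifetable, risk,
                                          t = NULL, threshold_mm = 55,
                                          grid_step = 0.25, horizon_age = 105,
                                          n_mc = 1000, seed = NULL,
                                          ely_variant = "literal", gl = 7,
                                          theta_uncertainty = TRUE) {
  if (is.null(t)) t <- if (length(subject$times)) max(subject$times) else 0
  eng <- .decision_engine(fit, subject, lifetable, risk, t, grid_step,
                          horizon_age, n_mc, seed, ely_variant, gl,
                          theta_uncertainty)
  grid <- eng$grid
  n_grid <- length(grid)
  n_mc <- ncol(eng$ELY)
  thr_idx <- integer(n_mc)
  for (k in seq_len(n_mc)) {
    j <- which(eng$M[, k] >= threshold_mm)
    thr_idx[k] <- if (length(j)) j[1] else n_grid   # never crosses: never operate
  }
  ely_thr <- eng$ELY[cbind(thr_idx, seq_len(n_mc))]
  ely_opt <- apply(eng$ELY, 2, max)
  structure(list(ely_opt = mean(ely_opt), ely_threshold = mean(ely_thr),
                 difference = mean(ely_opt - ely_thr),
                 pct_gain = 100 * mean(ely_opt - ely_thr) / mean(ely_opt),
                 threshold_mm = threshold_mm,
                 tx_threshold_draws = grid[thr_idx],
                 t = t, n_mc = n_mc, seed = seed),
            class = "aaa_policy_comparison")
}

#' @export
print.aaa_policy_comparison <- function(x, ...) {
  cat(sprintf("Policy comparison (threshold %.0f mm, %d MC draws)\n",
              x$threshold_mm, x$n_mc))
  cat(sprintf("  E[life-years] optimal:   %.3f\n", x$ely_opt))
  cat(sprintf("  E[life-years] threshold: %.3f\n", x$ely_threshold))
  cat(sprintf("  difference: %.3f years (%.1f%% of remaining life-years)\n",
              x$difference, x$pct_gain))
  invisible(x)
}
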