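# Dynamic, individualised prediction. The posterior of a subject's random
# effects given survival to the landmark time t and the measurements up to
# t is sampled by an independence Metropolis-Hastings step with a
# multivariate-t proposal centred at the conditional mode, while parameter
# uncertainty is propagated by drawing the parameter vector from the
# asymptotic normal distribution of the estimates at each iteration.

# log posterior (up to a constant) of b given survival to t and the
# measurements at times <= t; returns the density closure plus analytic
# gradient/curvature pieces for mode finding
.subject_logpost <- function(params, subject, t, gl = 15) {
  use <- subject$times <= t + 1e-9
  ti <- subject$times[use]
  yi <- subject$diameters[use]
  q <- params$spec$q
  Sinv <- solve(params$Sigma)
  sig2e <- params$sigma_eps^2
  w <- subject$w

  has_meas <- length(ti) > 0
  if (has_meas) {
    Z <- .traj_zmat(q, ti)
    r0 <- yi - drop(.traj_xmat(params$spec$degree, ti) %*% params$beta)
    ZtZ <- crossprod(Z)
  }
  if (t > 0) {
    rule <- .gl_rule(gl)
    s <- t * rule$x
    wgl <- t * rule$w
    lin <- .assoc_lin(params, s)
    off <- if (length(w)) sum(params$gamma * w) else 0
    base_s <- .log_h0(params, s) + off + lin$lin0
    linB_s <- lin$linB
  }

  g <- function(b) {
    val <- -0.5 * drop(b %*% Sinv %*% b)
    if (has_meas) {
      r <- r0 - drop(Z %*% b)
      val <- val - 0.5 * sum(r^2) / sig2e
    }
    if (t > 0) val <- val - sum(wgl * exp(base_s + drop(linB_s %*% b)))
    val
  }
  grad <- function(b) {
    gr <- -drop(Sinv %*% b)
    if (has_meas) gr <- gr + drop(crossprod(Z, r0 - drop(Z %*% b))) / sig2e
    if (t > 0) {
      hs <- exp(base_s + drop(linB_s %*% b))
      gr <- gr - drop(crossprod(linB_s, wgl * hs))
    }
    gr
  }
  neghess <- function(b) {
    nh <- Sinv
    if (has_meas) nh <- nh + ZtZ / sig2e
    if (t > 0) {
      hs <- exp(base_s + drop(linB_s %*% b))
      nh <- nh + crossprod(linB_s, (wgl * hs) * linB_s)
    }
    nh
  }

  # damped Newton; g is strictly concave
  b <- rep(0, q)
  gv <- g(b)
  for (it in 1:100) {
    gr <- grad(b)
    step <- solve(neghess(b), gr)
    sz <- 1
    repeat {
      bn <- b + sz * step
      gn <- g(bn)
      if (is.finite(gn) && gn >= gv - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-10) { bn <- b; gn <- gv; break }
    }
    b <- bn
    if (sqrt(sum(grad(b)^2)) < 1e-10 || abs(gn - gv) < 1e-13) { gv <- gn; break }
    gv <- gn
  }
  list(g = g, mode = b, C = solve(neghess(b)), has_meas = has_meas)
}

.dmvt_log <- function(x, mu, Lchol, df) {
  q <- length(mu)
  z <- forwardsolve(Lchol, x - mu)
  -0.5 * (df + q) * log1p(sum(z^2) / df) - sum(log(diag(Lchol)))
}

.rmvt <- function(mu, Lchol, df) {
  q <- length(mu)
  mu + drop(Lchol %*% stats::rnorm(q)) / sqrt(stats::rchisq(1, df) / df)
}

#' Draw from the posterior of a subject's random effects
#'
#' Samples pairs `(theta*, b*)`: the parameter vector from the asymptotic
#' normal distribution of the estimates (on the unconstrained scale), and
#' the random effects from `p(b | T > t, Y(t), theta*)` by a single
#' independence Metropolis-Hastings step per iteration against a
#' multivariate-t proposal centred at the conditional mode under the point
#' estimates.
#'
#' @param fit An `aaa_jm_fit`.
#' @param subject A [subject_history()]; only measurements at times `<= t`
#'   are used (landmark convention).
#' @param t Conditioning (landmark) time in years; the subject is assumed
#'   rupture-free at `t`.
#' @param n Number of draws.
#' @param seed Optional RNG seed for reproducibility.
#' @param df Degrees of freedom of the t proposal (default 4).
#' @param theta_uncertainty Propagate parameter uncertainty? If `FALSE`,
#'   all draws use the point estimates.
#' @param gl Gauss-Legendre order for the survival factor.
#' @return An object of class `aaa_b_draws`: matrix `b` (`n` x q), list
#'   `params` of per-draw parameter objects, and the MH `acceptance` rate.
#' @export
posterior_b_draws <- function(fit, subject, t, n = 1000, seed = NULL,
                              df = 4, theta_uncertainty = TRUE, gl = 15) {
  stopifnot(inherits(fit, "aaa_jm_fit"), inherits(subject, "aaa_subject"))
  if (t < 0) stop("t must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (!any(subject$times <= t + 1e-9))
    warning("no measurements at or before t = ", t,
            "; conditioning on survival alone")
  post <- .subject_logpost(fit$params, subject, t, gl = gl)
  Cs <- (post$C + t(post$C)) / 2
  # modest inflation so the proposal dominates the target in the tails
  L <- t(chol(2 * Cs))
  q <- fit$params$spec$q

  phi_draws <- if (theta_uncertainty) .draw_phi(fit, n)
               else matrix(rep(fit$phi[fit$free], each = n), nrow = n)
  b_cur <- post$mode
  lq_cur <- .dmvt_log(b_cur, post$mode, L, df)
  g_cur <- post$g(b_cur)
  B <- matrix(NA_real_, n, q)
  plist <- vector("list", n)
  acc <- 0L
  for (k in seq_len(n)) {
    pk <- try(.phi_draw_to_params(fit, phi_draws[k, ]), silent = TRUE)
    if (inherits(pk, "try-error")) pk <- fit$params  # invalid draw: fall back
    gk <- .subject_logpost_fun(pk, subject, t, gl)
    g_cur <- gk(b_cur)
    b_prop <- .rmvt(post$mode, L, df)
    lq_prop <- .dmvt_log(b_prop, post$mode, L, df)
    g_prop <- gk(b_prop)
    if (is.finite(g_prop) &&
        log(stats::runif(1)) < (g_prop - lq_prop) - (g_cur - lq_cur)) {
      b_cur <- b_prop
      lq_cur <- lq_prop
      acc <- acc + 1L
    }
    B[k, ] <- b_cur
    plist[[k]] <- pk
  }
  structure(list(b = B, params = plist, acceptance = acc / n,
                 mode = post$mode, C = Cs, t = t,
                 subject_id = subject$subject_id, seed = seed),
            class = "aaa_b_draws")
}

# log-posterior closure only (no mode finding) for a given parameter draw
.subject_logpost_fun <- function(params, subject, t, gl = 15) {
  use <- subject$times <= t + 1e-9
  ti <- subject$times[use]
  yi <- subject$diameters[use]
  q <- params$spec$q
  Sinv <- solve(params$Sigma)
  sig2e <- params$sigma_eps^2
  has_meas <- length(ti) > 0
  if (has_meas) {
    Z <- .traj_zmat(q, ti)
    r0 <- yi - drop(.traj_xmat(params$spec$degree, ti) %*% params$beta)
  }
  if (t > 0) {
    rule <- .gl_rule(gl)
    s <- t * rule$x
    wgl <- t * rule$w
    lin <- .assoc_lin(params, s)
    off <- if (length(subject$w)) sum(params$gamma * subject$w) else 0
    base_s <- .log_h0(params, s) + off + lin$lin0
    linB_s <- lin$linB
  }
  function(b) {
    val <- -0.5 * drop(b %*% Sinv %*% b)
    if (has_meas) {
      r <- r0 - drop(Z %*% b)
      val <- val - 0.5 * sum(r^2) / sig2e - 0.5 * length(r) * log(sig2e)
    }
    if (t > 0) val <- val - sum(wgl * exp(base_s + drop(linB_s %*% b)))
    val - 0.5 * determinant(params$Sigma)$modulus[1]
  }
}

#' Conditional probability of rupture given survival and history
#'
#' Computes the dynamic prediction
#' `F(u | t) = 1 - E[ S(u | b) / S(t | b) ]`, the probability of rupture by
#' future time `u` given rupture-free survival to `t` and the measurement
#' history up to `t`, with the expectation over the posterior of the random
#' effects and the asymptotic distribution of the parameter estimates.
#' Percentile bands across the Monte-Carlo draws quantify uncertainty.
#'
#' @inheritParams posterior_b_draws
#' @param grid_u Future times (years since entry), all `>= t`.
#' @param n_mc Monte-Carlo iterations (default 1000).
#' @param level Band coverage (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param gl Gauss-Legendre order per grid segment for the cumulative
#'   hazard.
#' @param draws Optionally, a precomputed [posterior_b_draws()] object.
#' @return An object of class `aaa_risk_curve` with the grid, mean risk,
#'   bands, and the per-draw risk matrix (`F_draws`).
#' @export
conditional_rupture_prob <- function(fit, subject, t, grid_u, n_mc = 1000,
                                     seed = NULL, level = 0.95, gl = 7,
                                     theta_uncertainty = TRUE, draws = NULL) {
  if (!length(grid_u)) stop("grid_u must be non-empty")
  if (any(grid_u < t - 1e-9)) stop("grid_u must be >= t")
  grid_u <- sort(grid_u)
  if (is.null(draws))
    draws <- posterior_b_draws(fit, subject, t, n = n_mc, seed = seed,
                               theta_uncertainty = theta_uncertainty)
  n_mc <- nrow(draws$b)
  FD <- matrix(0, length(grid_u), n_mc)
  pos <- grid_u > t + 1e-12
  for (k in seq_len(n_mc)) {
    if (any(pos)) {
      H <- .cum_hazard_grid(draws$params[[k]], draws$b[k, ], t,
                            grid_u[pos], w = subject$w, gl = gl)
      FD[pos, k] <- 1 - exp(-H)
    }
  }
  a <- (1 - level) / 2
  structure(list(t = t, grid_u = grid_u,
                 mean_risk = rowMeans(FD),
                 lower = apply(FD, 1, stats::quantile, probs = a),
                 upper = apply(FD, 1, stats::quantile, probs = 1 - a),
                 F_draws = FD, draws = draws, n_mc = n_mc, seed = seed,
                 level = level, subject_id = subject$subject_id),
            class = "aaa_risk_curve")
}

#' @export
print.aaa_risk_curve <- function(x, ...) {
  cat(sprintf("Conditional rupture risk for subject %s from t = %.2f y (%d MC draws)\n",
              as.character(x$subject_id), x$t, x$n_mc))
  i <- unique(round(seq(1, length(x$grid_u), length.out = 6)))
  print(data.frame(u_years = x$grid_u[i], mean = signif(x$mean_risk[i], 3),
                   lower = signif(x$lower[i], 3), upper = signif(x$upper[i], 3)))
  invisible(x)
}

#' @export
plot.aaa_risk_curve <- function(x, ...) {
  graphics::plot(x$grid_u, x$mean_risk, type = "l", ylim = c(0, max(x$upper)),
                 xlab = "Years since study entry",
                 ylab = "Conditional rupture probability", ...)
  graphics::lines(x$grid_u, x$lower, lty = 2)
  graphics::lines(x$grid_u, x$upper, lty = 2)
  invisible(x)
}

#' Predicted latent diameter trajectory with uncertainty
#'
#' Evaluates `m(u; beta*, b*)` across the Monte-Carlo draws, giving the
#' posterior predicted trajectory and percentile bands. As low-growth
#' measurements accrue, the predicted slope shrinks from the population
#' growth rate towards the subject's observed rate.
#'
#' @inheritParams conditional_rupture_prob
#' @return A data frame with columns `u_years`, `mean`, `lower`, `upper`,
#'   plus attribute `"slope_draws"`: per-draw growth rate at `t`.
#' @export
predict_trajectory <- function(fit, subject, t, grid_u, n_mc = 1000,
                               seed = NULL, level = 0.95,
                               theta_uncertainty = TRUE, draws = NULL) {
  if (!length(grid_u)) stop("grid_u must be non-empty")
  if (is.null(draws))
    draws <- posterior_b_draws(fit, subject, t, n = n_mc, seed = seed,
                               theta_uncertainty = theta_uncertainty)
  n_mc <- nrow(draws$b)
  M <- matrix(NA_real_, length(grid_u), n_mc)
  sl <- numeric(n_mc)
  for (k in seq_len(n_mc)) {
    M[, k] <- traj_value(draws$params[[k]], draws$b[k, ], grid_u)
    sl[k] <- traj_slope(draws$params[[k]], draws$b[k, ], t)
  }
  a <- (1 - level) / 2
  out <- data.frame(u_years = grid_u, mean = rowMeans(M),
                    lower = apply(M, 1, stats::quantile, probs = a),
                    upper = apply(M, 1, stats::quantile, probs = 1 - a))
  attr(out, "slope_draws") <- sl
  attr(out, "draws") <- draws
  out
}
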