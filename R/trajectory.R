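# Latent trajectory evaluation: value, slope and cumulative area, all
# linear in the random effects b, which is what makes the hazard linear
# predictor decompose as lin0(t) + linB(t) %*% b throughout the package.

.traj_xmat <- function(degree, t) {
  if (degree == 1L) cbind(1, t) else cbind(1, t, t^2)
}

.traj_zmat <- function(q, t) {
  if (q == 1L) cbind(rep(1, length(t))) else cbind(1, t)
}

#' Evaluate the latent diameter trajectory
#'
#' Computes `m_i(t) = x(t)' beta + z(t)' b`, the true (error-free) diameter
#' in mm of a subject with random effects `b` at time `t` years after study
#' entry.
#'
#' @param params An [jm_params()] object.
#' @param b Random-effect vector of length `params$spec$q`.
#' @param t Time(s) since study entry, years; vectorised.
#' @return Numeric vector of diameters (mm).
#' @export
#' @examples
#' p <- aaa_growth_params()
#' traj_value(p, c(0, 0), 0)  # population intercept, 36.5 mm
traj_value <- function(params, b, t) {
  b <- .check_b(params, b)
  stopifnot(all(t >= 0))
  drop(.traj_xmat(params$spec$degree, t) %*% params$beta +
         .traj_zmat(params$spec$q, t) %*% b)
}

#' Evaluate the trajectory growth rate
#'
#' `d/dt m_i(t)` in mm/year: `(beta1 + b1) + 2 beta2 t` for the quadratic
#' trend (constant in `t` for the linear trend).
#'
#' @inheritParams traj_value
#' @return Numeric vector of growth rates (mm/year).
#' @export
traj_slope <- function(params, b, t) {
  b <- .check_b(params, b)
  stopifnot(all(t >= 0))
  sl <- rep(params$beta[2], length(t))
  if (params$spec$degree == 2L) sl <- sl + 2 * params$beta[3] * t
  if (params$spec$q == 2L) sl <- sl + b[2]
  sl
}

#' Evaluate the cumulative trajectory (area under the growth curve)
#'
#' Closed-form polynomial integral `int_0^t m_i(s) ds` in mm-years, the
#' cumulative-burden feature available to the association structure.
#'
#' @inheritParams traj_value
#' @return Numeric vector (mm-years).
#' @export
traj_cum <- function(params, b, t) {
  b <- .check_b(params, b)
  stopifnot(all(t >= 0))
  beta <- params$beta
  out <- beta[1] * t + beta[2] * t^2 / 2
  if (params$spec$degree == 2L) out <- out + beta[3] * t^3 / 3
  out <- out + b[1] * t
  if (params$spec$q == 2L) out <- out + b[2] * t^2 / 2
  out
}

# Association linear predictor pieces at times t:
#   alpha' f(m(t)) = lin0(t) + linB(t) %*% b
# with linB a length(t) x q matrix. Used by the hazard, the likelihood
# mode-finder and the posterior sampler.
.assoc_lin <- function(params, t) {
  spec <- params$spec
  beta <- params$beta
  q <- spec$q
  n <- length(t)
  kind <- params$assoc$kind
  a <- params$assoc$alpha

  v0 <- drop(.traj_xmat(spec$degree, t) %*% beta)
  vB <- .traj_zmat(q, t)

  s0 <- rep(beta[2], n)
  if (spec$degree == 2L) s0 <- s0 + 2 * beta[3] * t
  sB <- if (q == 2L) cbind(0, rep(1, n)) else cbind(rep(0, n))

  c0 <- beta[1] * t + beta[2] * t^2 / 2
  if (spec$degree == 2L) c0 <- c0 + beta[3] * t^3 / 3
  cB <- if (q == 2L) cbind(t, t^2 / 2) else cbind(t)

  switch(kind,
    current_value = list(lin0 = a[1] * v0, linB = a[1] * vB),
    slope_only = list(lin0 = a[1] * s0, linB = a[1] * sB),
    value_and_slope = list(lin0 = a[1] * v0 + a[2] * s0,
                           linB = a[1] * vB + a[2] * sB),
    value_and_cumulative = list(lin0 = a[1] * v0 + a[2] * c0,
                                linB = a[1] * vB + a[2] * cB))
}
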