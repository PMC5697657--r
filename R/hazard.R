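# Rupture hazard, cumulative hazard and survivor function for a subject
# with known random effects. The cumulative hazard has no closed form when
# the trajectory enters the log-hazard (exp of a polynomial), so it is
# integrated by fixed-order Gauss-Legendre quadrature.

# cache of Gauss-Legendre rules on [0, 1]
.gl_cache <- new.env(parent = emptyenv())

.gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

# log h0(t); weibull parameterised as h0(t) = exp(log_scale) * k * t^(k-1)
.log_h0 <- function(params, t) {
  bl <- params$baseline
  if (bl$kind == "exponential") {
    rep(bl$log_h0, length(t))
  } else {
    k <- exp(bl$log_shape)
    bl$log_scale + bl$log_shape + (k - 1) * log(t)
  }
}

#' Rupture hazard at time t
#'
#' `h_i(t) = h0(t) exp(gamma' w + alpha' f(m_i(t)))` per year, for a subject
#' with random effects `b` and baseline covariates `w`.
#'
#' @inheritParams traj_value
#' @param w Baseline covariate vector (must match `length(params$gamma)`;
#'   default none).
#' @return Hazard per year at each `t` (vectorised).
#' @export
#' @examples
#' p <- aaa_growth_params()
#' hazard(p, c(0, 0), 4)  # hazard 4 years into surveillance
hazard <- function(params, b, t, w = numeric(0)) {
  exp(.log_hazard(params, .check_b(params, b), t, w))
}

.log_hazard <- function(params, b, t, w = numeric(0)) {
  if (length(w) != length(params$gamma))
    stop("w must match length(gamma)")
  lin <- .assoc_lin(params, t)
  off <- if (length(w)) sum(params$gamma * w) else 0
  .log_h0(params, t) + off + lin$lin0 + drop(lin$linB %*% b)
}

#' Cumulative rupture hazard over an interval
#'
#' `int_{t0}^{t1} h_i(s) ds` by `gl`-point Gauss-Legendre quadrature.
#' Additive over abutting intervals and exact (up to quadrature error,
#' which is negligible at the default order for these smooth hazards).
#'
#' @inheritParams hazard
#' @param t0,t1 Interval endpoints in years, `0 <= t0 <= t1`.
#' @param gl Number of Gauss-Legendre nodes (default 15).
#' @return Nonnegative scalar.
#' @export
cum_hazard <- function(params, b, t0, t1, w = numeric(0), gl = 15) {
  if (t1 < t0 || t0 < 0) stop("need 0 <= t0 <= t1")
  if (t1 == t0) return(0)
  b <- .check_b(params, b)
  rule <- .gl_rule(gl)
  s <- t0 + (t1 - t0) * rule$x
  sum((t1 - t0) * rule$w * exp(.log_hazard(params, b, s, w)))
}

# cumulative hazard from `from` to each grid point (grid nondecreasing,
# grid[1] >= from); per-segment GL, fully vectorised over segments
.cum_hazard_grid <- function(params, b, from, grid, w = numeric(0), gl = 7) {
  stopifnot(all(diff(grid) >= 0), grid[1] >= from)
  rule <- .gl_rule(gl)
  lo <- c(from, grid[-length(grid)])
  hi <- grid
  len <- hi - lo
  # nodes: n_seg x gl matrix
  s <- outer(lo, rep(1, gl)) + outer(len, rule$x)
  hvals <- exp(.log_hazard(params, b, as.vector(s), w))
  seg <- drop(matrix(hvals, nrow = length(lo)) %*% rule$w) * len
  cumsum(seg)
}

#' Rupture-free survivor function
#'
#' `S_i(t) = exp(-int_0^t h_i(s) ds)`: the probability, conditional on the
#' random effects, that no rupture has occurred by time `t`.
#'
#' @inheritParams cum_hazard
#' @param t Time in years (scalar).
#' @return Probability in (0, 1].
#' @export
survivor <- function(params, b, t, w = numeric(0), gl = 15) {
  exp(-cum_hazard(params, b, 0, t, w, gl))
}
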