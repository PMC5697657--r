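#' Trajectory specification for the growth sub-model
#'
#' Describes the fixed-effects polynomial time trend of the latent diameter
#' trajectory and which of its terms carry subject-level random effects.
#' The default (quadratic fixed trend, random intercept and random linear
#' slope) is the form usually adopted for aneurysm growth over surveillance
#' time scales: growth accelerates slowly, but between-subject variation is
#' adequately captured by level and slope.
#'
#' @param degree Polynomial degree of the fixed time trend: 1 (linear) or
#'   2 (quadratic).
#' @param random Which terms carry random effects: `"intercept"` or
#'   `c("intercept", "linear")`. Random terms must be a subset of the fixed
#'   terms.
#' @return An object of class `aaa_trajectory_spec` with elements `degree`,
#'   `random` and `q` (the number of random effects).
#' @export
#' @examples
#' trajectory_spec(2, c("intercept", "linear"))
trajectory_spec <- function(degree = 2, random = c("intercept", "linear")) {
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 (linear) or 2 (quadratic)")
  random <- match.arg(random, c("intercept", "linear"), several.ok = TRUE)
  if (!"intercept" %in% random)
    stop("a random intercept is required")
  q <- length(unique(random))
  if (q == 2L && degree < 1L)
    stop("random linear term requires a fixed linear term")
  structure(list(degree = as.integer(degree),
                 random = unique(random),
                 q = as.integer(q)),
            class = "aaa_trajectory_spec")
}

.assoc_kinds <- c("current_value", "slope_only", "value_and_slope",
                  "value_and_cumulative")

.n_alpha <- function(kind) {
  switch(kind,
         current_value = 1L, slope_only = 1L,
         value_and_slope = 2L, value_and_cumulative = 2L)
}

#' Association structure linking trajectory and rupture hazard
#'
#' The rupture log-hazard is shifted by `alpha' f(m_i(t))`, where `f`
#' extracts features of the latent trajectory `m_i(t)`: its current value
#' (mm), its slope (mm/year), or its cumulative area since study entry
#' (mm-years). Coefficients are log hazard ratios per unit of the feature.
#'
#' @param kind One of `"current_value"`, `"slope_only"`,
#'   `"value_and_slope"`, `"value_and_cumulative"`.
#' @param alpha Numeric vector of association coefficients; length 1 for the
#'   single-feature kinds, length 2 otherwise (value first).
#' @return An object of class `aaa_association`.
#' @export
association <- function(kind = "value_and_slope", alpha) {
  kind <- match.arg(kind, .assoc_kinds)
  alpha <- as.numeric(alpha)
  if (length(alpha) != .n_alpha(kind))
    stop(sprintf("association '%s' needs %d coefficient(s), got %d",
                 kind, .n_alpha(kind), length(alpha)))
  structure(list(kind = kind, alpha = alpha), class = "aaa_association")
}

#' Joint model parameters
#'
#' Container for the full parameter vector of the joint growth/rupture
#' model: fixed effects of the diameter trajectory, residual measurement
#' error, random-effects covariance, baseline rupture hazard, optional
#' baseline-covariate log-hazard coefficients, and the association
#' structure.
#'
#' @param beta Fixed effects (mm, mm/year, mm/year^2): length `degree + 1`.
#' @param sigma_eps Residual (measurement error) SD in mm; positive.
#' @param sigma0 SD of the random intercept (mm); positive.
#' @param sigma1 SD of the random linear slope (mm/year); required when the
#'   spec has two random effects.
#' @param rho Correlation between random intercept and slope, in (-1, 1).
#' @param baseline Baseline hazard: `list(kind = "exponential", log_h0 = x)`
#'   giving a constant hazard `exp(log_h0)` per year, or
#'   `list(kind = "weibull", log_scale = l, log_shape = s)` giving
#'   `h0(t) = exp(l) * k * t^(k-1)` with `k = exp(s)`.
#' @param assoc An [association()] object.
#' @param gamma Log-hazard coefficients for baseline covariates `w`
#'   (default none).
#' @param spec A [trajectory_spec()].
#' @return An object of class `aaa_jm_params`.
#' @export
#' @examples
#' jm_params(beta = c(36.5, 2.05, 0.097), sigma_eps = 2.91,
#'           sigma0 = 6.63, sigma1 = 1.79, rho = 0.567,
#'           baseline = list(kind = "exponential", log_h0 = -11.0),
#'           assoc = association("value_and_slope", c(0.084, 0.579)))
jm_params <- function(beta, sigma_eps, sigma0, sigma1 = NULL, rho = 0,
                      baseline = list(kind = "exponential", log_h0 = -11),
                      assoc = association("value_and_slope", c(0.084, 0.579)),
                      gamma = numeric(0),
                      spec = trajectory_spec()) {
  stopifnot(inherits(spec, "aaa_trajectory_spec"),
            inherits(assoc, "aaa_association"))
  beta <- as.numeric(beta)
  if (length(beta) != spec$degree + 1L)
    stop(sprintf("beta must have length %d for degree %d",
                 spec$degree + 1L, spec$degree))
  if (sigma_eps <= 0) stop("sigma_eps must be positive")
  if (sigma0 <= 0) stop("sigma0 must be positive")
  if (spec$q == 2L) {
    if (is.null(sigma1) || sigma1 <= 0)
      stop("sigma1 must be positive when a random slope is present")
    if (abs(rho) >= 1) stop("rho must lie strictly in (-1, 1)")
    Sigma <- matrix(c(sigma0^2, rho * sigma0 * sigma1,
                      rho * sigma0 * sigma1, sigma1^2), 2, 2)
  } else {
    sigma1 <- NULL
    rho <- NULL
    Sigma <- matrix(sigma0^2, 1, 1)
  }
  baseline$kind <- match.arg(baseline$kind, c("exponential", "weibull"))
  if (baseline$kind == "exponential") {
    if (is.null(baseline$log_h0)) stop("exponential baseline needs log_h0")
  } else {
    if (is.null(baseline$log_scale) || is.null(baseline$log_shape))
      stop("weibull baseline needs log_scale and log_shape")
  }
  structure(list(spec = spec, beta = beta, sigma_eps = sigma_eps,
                 sigma0 = sigma0, sigma1 = sigma1, rho = rho, Sigma = Sigma,
                 baseline = baseline, assoc = assoc, gamma = as.numeric(gamma)),
            class = "aaa_jm_params")
}

#' Canonical small-aneurysm screening parameter set
#'
#' Parameter values representative of a large UK screening cohort of men
#' with small (30-54 mm) AAAs: quadratic growth with random intercept and
#' linear slope, exponential baseline rupture hazard, and log hazard ratios
#' of 0.084 per mm of current diameter and 0.579 per mm/year of growth
#' rate. Used as the default generating values for the cohort simulator
#' and as a realistic starting point for worked examples.
#'
#' @return An `aaa_jm_params` object.
#' @export
aaa_growth_params <- function() {
  jm_params(beta = c(36.5, 2.05, 0.097), sigma_eps = 2.91,
            sigma0 = 6.63, sigma1 = 1.79, rho = 0.567,
            baseline = list(kind = "exponential", log_h0 = -11.0),
            assoc = association("value_and_slope", c(0.084, 0.579)))
}

#' Reported standard errors accompanying [aaa_growth_params()]
#'
#' Standard errors for the estimable parameters of the canonical screening
#' parameter set, used to propagate parameter uncertainty when a fitted
#' covariance matrix is not available (e.g. when building an
#' [as_jm_fit()] object from published estimates).
#'
#' @return Named numeric vector of standard errors.
#' @export
aaa_growth_se <- function() {
  c(beta0 = 0.2, beta1 = 0.08, beta2 = 0.006,
    log_h0 = 0.9, alpha1 = 0.021, alpha2 = 0.193)
}

#' @export
print.aaa_jm_params <- function(x, ...) {
  cat("Joint AAA growth/rupture model parameters\n")
  cat(sprintf("  trajectory: degree %d, %d random effect(s)\n",
              x$spec$degree, x$spec$q))
  cat("  beta:      ", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  sigma_eps: ", signif(x$sigma_eps, 4), "mm\n")
  if (x$spec$q == 2L)
    cat(sprintf("  RE: sigma0 = %.3g, sigma1 = %.3g, rho = %.3g\n",
                x$sigma0, x$sigma1, x$rho))
  else
    cat(sprintf("  RE: sigma0 = %.3g\n", x$sigma0))
  if (x$baseline$kind == "exponential")
    cat(sprintf("  baseline hazard: exponential, log h0 = %.3g\n",
                x$baseline$log_h0))
  else
    cat(sprintf("  baseline hazard: weibull, log scale = %.3g, log shape = %.3g\n",
                x$baseline$log_scale, x$baseline$log_shape))
  cat(sprintf("  association (%s): %s\n", x$assoc$kind,
              paste(signif(x$assoc$alpha, 4), collapse = ", ")))
  if (length(x$gamma))
    cat("  gamma:     ", paste(signif(x$gamma, 4), collapse = ", "), "\n")
  invisible(x)
}

# validate a random-effect vector against the spec
.check_b <- function(params, b) {
  b <- as.numeric(b)
  if (length(b) != params$spec$q)
    stop(sprintf("random-effect vector has length %d; spec requires %d",
                 length(b), params$spec$q))
  b
}
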