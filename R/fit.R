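# Maximum-likelihood fitting of the joint model. The optimiser works on an
# unconstrained scale (log for SDs and the Weibull shape, atanh for the
# random-effects correlation); standard errors are mapped back to the
# natural scale by the delta method.

# template describing the layout of the unconstrained parameter vector phi
.phi_template <- function(spec, assoc_kind, baseline_kind, n_gamma = 0L) {
  nm <- paste0("beta", seq_len(spec$degree + 1L) - 1L)
  nm <- c(nm, "log_sigma_eps", "log_sigma0")
  if (spec$q == 2L) nm <- c(nm, "log_sigma1", "atanh_rho")
  nm <- if (baseline_kind == "exponential") c(nm, "log_h0")
        else c(nm, "log_scale", "log_shape")
  nm <- c(nm, paste0("alpha", seq_len(.n_alpha(assoc_kind))))
  if (n_gamma > 0L) nm <- c(nm, paste0("gamma", seq_len(n_gamma)))
  list(names = nm, spec = spec, assoc_kind = assoc_kind,
       baseline_kind = baseline_kind, n_gamma = as.integer(n_gamma))
}

.params_to_phi <- function(params) {
  phi <- c(params$beta, log(params$sigma_eps), log(params$sigma0))
  if (params$spec$q == 2L) phi <- c(phi, log(params$sigma1), atanh(params$rho))
  phi <- c(phi, .baseline_vec(params), params$assoc$alpha, params$gamma)
  tpl <- .phi_template(params$spec, params$assoc$kind, params$baseline$kind,
                       length(params$gamma))
  stats::setNames(phi, tpl$names)
}

.phi_to_params <- function(phi, tpl) {
  phi <- unname(phi)
  spec <- tpl$spec
  i <- spec$degree + 1L
  beta <- phi[seq_len(i)]
  sigma_eps <- exp(phi[i + 1L])
  sigma0 <- exp(phi[i + 2L])
  pos <- i + 2L
  if (spec$q == 2L) {
    sigma1 <- exp(phi[pos + 1L]); rho <- tanh(phi[pos + 2L]); pos <- pos + 2L
  } else {
    sigma1 <- NULL; rho <- 0
  }
  if (tpl$baseline_kind == "exponential") {
    baseline <- list(kind = "exponential", log_h0 = phi[pos + 1L]); pos <- pos + 1L
  } else {
    baseline <- list(kind = "weibull", log_scale = phi[pos + 1L],
                     log_shape = phi[pos + 2L]); pos <- pos + 2L
  }
  na <- .n_alpha(tpl$assoc_kind)
  alpha <- phi[pos + seq_len(na)]; pos <- pos + na
  gamma <- if (tpl$n_gamma > 0L) phi[pos + seq_len(tpl$n_gamma)] else numeric(0)
  jm_params(beta = unname(beta), sigma_eps = sigma_eps, sigma0 = sigma0,
            sigma1 = sigma1, rho = rho, baseline = baseline,
            assoc = association(tpl$assoc_kind, unname(alpha)),
            gamma = unname(gamma), spec = spec)
}

# natural-scale report vector (Table-2 style names)
.phi_to_natural <- function(phi, tpl) {
  p <- .phi_to_params(phi, tpl)
  out <- stats::setNames(p$beta, paste0("beta", seq_along(p$beta) - 1L))
  out <- c(out, .baseline_vec(p))
  names(out)[length(out) - (if (tpl$baseline_kind == "exponential") 0L else 1L):0] <-
    if (tpl$baseline_kind == "exponential") "log_h0" else c("log_scale", "log_shape")
  out <- c(out, stats::setNames(p$assoc$alpha,
                                paste0("alpha", seq_along(p$assoc$alpha))))
  if (length(p$gamma))
    out <- c(out, stats::setNames(p$gamma, paste0("gamma", seq_along(p$gamma))))
  out <- c(out, sigma0 = p$sigma0)
  if (p$spec$q == 2L) out <- c(out, sigma1 = p$sigma1, rho = p$rho)
  c(out, sigma_eps = p$sigma_eps)
}

# two-stage starting values: mixed model for the growth parameters, then a
# Poisson working model for the hazard with empirical Bayes trajectories
.init_phi <- function(cohort, tpl, gl) {
  spec <- tpl$spec
  long <- cohort$longitudinal
  long$id <- factor(long$subject_id)
  fml <- if (spec$degree == 2L)
    diameter_mm ~ time_years + I(time_years^2) else diameter_mm ~ time_years
  fml <- if (spec$q == 2L)
    stats::update(fml, . ~ . + (time_years | id)) else
    stats::update(fml, . ~ . + (1 | id))
  lf <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = long, REML = FALSE)))
  beta <- unname(lme4::fixef(lf))
  vc <- lme4::VarCorr(lf)$id
  sigma0 <- sqrt(vc[1, 1])
  sigma_eps <- stats::sigma(lf)
  if (spec$q == 2L) {
    sigma1 <- max(sqrt(vc[2, 2]), 1e-3)
    rho <- min(max(attr(vc, "correlation")[1, 2], -0.95), 0.95)
  }
  # EB trajectories at the observed event/censoring times
  re <- lme4::ranef(lf)$id
  ids <- match(as.character(cohort$survival$subject_id), rownames(re))
  base <- jm_params(beta = beta, sigma_eps = sigma_eps, sigma0 = sigma0,
                    sigma1 = if (spec$q == 2L) sigma1 else NULL,
                    rho = if (spec$q == 2L) rho else 0,
                    baseline = list(kind = "exponential", log_h0 = -10),
                    assoc = association(tpl$assoc_kind,
                                        rep(0, .n_alpha(tpl$assoc_kind))),
                    spec = spec)
  Tobs <- cohort$survival$obs_time_years
  feats <- t(vapply(seq_along(ids), function(i) {
    b <- as.numeric(re[ids[i], seq_len(spec$q)])
    tt <- max(Tobs[i], 1e-3)
    switch(tpl$assoc_kind,
      current_value = traj_value(base, b, tt),
      slope_only = traj_slope(base, b, tt),
      value_and_slope = c(traj_value(base, b, tt), traj_slope(base, b, tt)),
      value_and_cumulative = c(traj_value(base, b, tt), traj_cum(base, b, tt)))
  }, numeric(.n_alpha(tpl$assoc_kind))))
  if (.n_alpha(tpl$assoc_kind) == 1L) feats <- matrix(feats, ncol = 1L)
  dat <- data.frame(d = cohort$survival$event, off = log(pmax(Tobs, 1e-3)))
  gfit <- try(suppressWarnings(
    stats::glm(d ~ . - off + offset(off), family = stats::poisson(),
               data = cbind(dat, as.data.frame(feats)))), silent = TRUE)
  if (inherits(gfit, "try-error") || any(!is.finite(stats::coef(gfit)))) {
    log_h0 <- log(max(sum(dat$d), 0.5) / sum(Tobs))
    alpha <- rep(0, .n_alpha(tpl$assoc_kind))
  } else {
    cf <- stats::coef(gfit)
    log_h0 <- min(max(cf[1], -25), 0)
    alpha <- pmin(pmax(cf[-1], -2), 2)
  }
  phi <- c(beta, log(sigma_eps), log(sigma0))
  if (spec$q == 2L) phi <- c(phi, log(sigma1), atanh(rho))
  phi <- if (tpl$baseline_kind == "exponential") c(phi, log_h0)
         else c(phi, log_h0, 0)
  phi <- c(phi, alpha)
  if (tpl$n_gamma > 0L) phi <- c(phi, rep(0, tpl$n_gamma))
  stats::setNames(phi, tpl$names)
}

#' Fit the joint AAA growth and rupture model
#'
#' Maximises the adaptive Gauss-Hermite likelihood (see [joint_loglik()])
#' over all free parameters using a quasi-Newton search on an unconstrained
#' parameterisation. Standard errors come from the numeric Hessian of the
#' negative log-likelihood at the maximum, mapped to the natural scale by
#' the delta method. Starting values default to a two-stage fit: a linear
#' mixed model for the growth parameters, then a Poisson working model for
#' the hazard with empirical Bayes trajectories plugged in.
#'
#' @param cohort An [aaa_cohort()].
#' @param spec A [trajectory_spec()].
#' @param assoc_kind Association structure; see [association()].
#' @param baseline `"exponential"` (default) or `"weibull"` baseline hazard.
#' @param init Optional starting values: an `aaa_jm_params` object.
#' @param fixed Named list of parameters to hold fixed at given values, on
#'   the natural scale, using the unconstrained-scale names (e.g.
#'   `list(log_h0 = -30, alpha1 = 0, alpha2 = 0)` to switch the event
#'   sub-model off).
#' @param gh,gl Quadrature orders; see [joint_loglik()].
#' @param hessian Compute the numeric Hessian (needed for standard errors
#'   and for parameter uncertainty in predictions)? Default `TRUE`.
#' @param control Passed to [stats::optim()] (method `"BFGS"`).
#' @return An object of class `aaa_jm_fit` with elements `params`,
#'   `estimates` (natural scale), `se`, `vcov`, `log_lik`, `aic`,
#'   `converged`, and per-subject empirical Bayes modes (`eb`).
#' @export
fit_joint_model <- function(cohort, spec = trajectory_spec(),
                            assoc_kind = "value_and_slope",
                            baseline = c("exponential", "weibull"),
                            init = NULL, fixed = list(),
                            gh = 9, gl = 15, hessian = TRUE,
                            control = list(maxit = 400, reltol = 1e-10)) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  baseline <- match.arg(baseline)
  assoc_kind <- match.arg(assoc_kind, .assoc_kinds)
  n_events <- sum(cohort$survival$event)
  if (n_events == 0 && !("log_h0" %in% names(fixed)))
    warning("no rupture events in the cohort; the survival sub-model is ",
            "weakly identified")
  tpl <- .phi_template(spec, assoc_kind, baseline, 0L)
  phi0 <- if (is.null(init)) .init_phi(cohort, tpl, gl)
          else .params_to_phi(init)
  if (length(phi0) != length(tpl$names))
    stop("init does not match the requested model structure")
  names(phi0) <- tpl$names

  # fixed parameters: natural-scale values, unconstrained-scale names
  fix_idx <- match(names(fixed), tpl$names)
  if (anyNA(fix_idx)) stop("unknown parameter in 'fixed': ",
                           paste(names(fixed)[is.na(fix_idx)], collapse = ", "))
  phi_fix <- phi0
  for (k in seq_along(fixed)) {
    nm <- names(fixed)[k]; v <- fixed[[k]]
    phi_fix[fix_idx[k]] <- if (grepl("^log_sigma", nm)) log(v)
                           else if (nm == "atanh_rho") atanh(v) else v
  }
  free <- !(seq_along(phi0) %in% fix_idx)
  phi_full <- phi_fix

  negll <- function(phi_free) {
    phi_full[free] <- phi_free
    p <- try(.phi_to_params(phi_full, tpl), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    v <- try(joint_loglik(cohort, p, gh = gh, gl = gl), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    -v
  }

  opt <- stats::optim(phi_fix[free], negll, method = "BFGS", control = control)
  phi_hat <- phi_fix
  phi_hat[free] <- opt$par
  params_hat <- .phi_to_params(phi_hat, tpl)
  ll <- joint_loglik(cohort, params_hat, gh = gh, gl = gl, details = TRUE)
  npar <- sum(free)
  converged <- opt$convergence == 0

  vcov_phi <- matrix(NA_real_, npar, npar)
  if (hessian && npar > 0) {
    H <- pracma::hessian(negll, opt$par)
    vc <- try(solve((H + t(H)) / 2), silent = TRUE)
    if (inherits(vc, "try-error") || any(!is.finite(vc)) ||
        any(diag(vc) <= 0)) {
      vc <- try(pracma::pinv((H + t(H)) / 2), silent = TRUE)
      if (inherits(vc, "try-error")) vc <- matrix(NA_real_, npar, npar)
      else converged <- converged && all(diag(vc) > 0)
    }
    vcov_phi <- vc
  }
  dimnames(vcov_phi) <- list(tpl$names[free], tpl$names[free])

  nat_fun <- function(pf) { phi_full[free] <- pf; .phi_to_natural(phi_full, tpl) }
  est <- nat_fun(opt$par)
  se <- rep(NA_real_, length(est))
  vcov_nat <- matrix(NA_real_, length(est), length(est),
                     dimnames = list(names(est), names(est)))
  if (hessian && all(is.finite(vcov_phi))) {
    J <- pracma::jacobian(nat_fun, opt$par)
    vcov_nat[] <- J %*% vcov_phi %*% t(J)
    se <- sqrt(pmax(diag(vcov_nat), 0))
  }
  names(se) <- names(est)

  structure(list(params = params_hat, estimates = est, se = se,
                 vcov = vcov_nat, vcov_phi = vcov_phi,
                 phi = phi_hat, free = free, template = tpl,
                 log_lik = ll$loglik, aic = -2 * ll$loglik + 2 * npar,
                 npar = npar, converged = converged,
                 optim = list(convergence = opt$convergence,
                              counts = opt$counts, message = opt$message),
                 eb = list(modes = ll$modes, cov = ll$mode_cov,
                           subject_id = ll$subject_id),
                 n = nrow(cohort$survival), n_events = n_events,
                 gh = gh, gl = gl, call = match.call()),
            class = "aaa_jm_fit")
}

#' Build a fit-like object from known parameter values
#'
#' Constructs an `aaa_jm_fit` from externally supplied estimates (for
#' example, published parameter values) so that the prediction and decision
#' machinery can be used without refitting. Parameter uncertainty is taken
#' from `se`, treated as independent on the unconstrained scale; parameters
#' without a supplied standard error are treated as known exactly.
#'
#' @param params An [jm_params()] object.
#' @param se Named numeric vector of standard errors on the scale of the
#'   reported parameters (see [aaa_growth_se()] for the canonical set).
#' @return An `aaa_jm_fit` object (with `log_lik`/`aic` set to `NA`).
#' @export
as_jm_fit <- function(params, se = aaa_growth_se()) {
  stopifnot(inherits(params, "aaa_jm_params"))
  tpl <- .phi_template(params$spec, params$assoc$kind, params$baseline$kind,
                       length(params$gamma))
  phi <- .params_to_phi(params)
  # map natural-scale SEs onto phi entries; SD/correlation SEs, if given,
  # are converted by the inverse-transform delta method
  sds <- stats::setNames(rep(0, length(phi)), tpl$names)
  for (nm in names(se)) {
    v <- se[[nm]]
    tr <- switch(nm,
      sigma_eps = c("log_sigma_eps", v / params$sigma_eps),
      sigma0 = c("log_sigma0", v / params$sigma0),
      sigma1 = if (!is.null(params$sigma1)) c("log_sigma1", v / params$sigma1),
      rho = if (!is.null(params$rho)) c("atanh_rho", v / (1 - params$rho^2)),
      if (nm %in% tpl$names) c(nm, v))
    if (!is.null(tr)) sds[tr[1]] <- as.numeric(tr[2])
  }
  est <- .phi_to_natural(phi, tpl)
  structure(list(params = params, estimates = est,
                 se = stats::setNames(rep(NA_real_, length(est)), names(est)),
                 vcov = NULL, vcov_phi = diag(sds^2, length(phi)),
                 phi = phi, free = rep(TRUE, length(phi)), template = tpl,
                 log_lik = NA_real_, aic = NA_real_, npar = length(phi),
                 converged = TRUE, optim = NULL, eb = NULL,
                 n = NA_integer_, n_events = NA_integer_,
                 gh = 9, gl = 15, call = match.call()),
            class = "aaa_jm_fit")
}

#' @export
print.aaa_jm_fit <- function(x, digits = 4, ...) {
  cat("Joint AAA growth/rupture model fit\n")
  if (!is.na(x$n))
    cat(sprintf("  %d subjects, %d rupture events\n", x$n, x$n_events))
  cat(sprintf("  trajectory degree %d, %d random effect(s); association: %s; baseline: %s\n",
              x$params$spec$degree, x$params$spec$q, x$params$assoc$kind,
              x$params$baseline$kind))
  if (!is.na(x$log_lik))
    cat(sprintf("  log-lik = %.2f, AIC = %.2f, converged: %s\n",
                x$log_lik, x$aic, x$converged))
  tab <- data.frame(Estimate = signif(x$estimates, digits),
                    SE = signif(x$se, digits))
  print(tab)
  invisible(x)
}

#' @export
logLik.aaa_jm_fit <- function(object, ...) {
  structure(object$log_lik, df = object$npar, class = "logLik")
}

#' @export
vcov.aaa_jm_fit <- function(object, ...) object$vcov

#' @export
coef.aaa_jm_fit <- function(object, ...) object$estimates

#' Wald hazard ratio and confidence interval
#'
#' Exponentiates a log-hazard coefficient and its Wald limits.
#'
#' @param estimate Log hazard ratio.
#' @param se Standard error (>= 0).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(hr, lower, upper)`.
#' @export
#' @examples
#' wald_hr(0.084, 0.021)  # HR per mm of current diameter
wald_hr <- function(estimate, se, level = 0.95) {
  if (se < 0) stop("se must be >= 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(hr = exp(estimate), lower = exp(estimate - z * se),
    upper = exp(estimate + z * se))
}

# draw parameter vectors from the asymptotic distribution of the estimates
.draw_phi <- function(fit, n) {
  V <- fit$vcov_phi
  phi_free <- fit$phi[fit$free]
  if (is.null(V) || any(!is.finite(V)) || all(V == 0)) {
    matrix(rep(phi_free, each = n), nrow = n,
           dimnames = list(NULL, names(phi_free)))
  } else {
    ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
    R <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
    sweep(matrix(stats::rnorm(n * length(phi_free)), n) %*% t(R), 2,
          phi_free, `+`)
  }
}

.phi_draw_to_params <- function(fit, phi_free) {
  phi <- fit$phi
  phi[fit$free] <- phi_free
  .phi_to_params(phi, fit$template)
}
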