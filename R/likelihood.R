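# R-side interface to the adaptive Gauss-Hermite joint likelihood.

.gh_cache <- new.env(parent = emptyenv())

.gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

.assoc_code <- function(kind) {
  match(kind, .assoc_kinds) - 1L
}

.baseline_vec <- function(params) {
  bl <- params$baseline
  if (bl$kind == "exponential") bl$log_h0 else c(bl$log_scale, bl$log_shape)
}

.gamma_offsets <- function(cohort, params) {
  if (!length(params$gamma)) return(numeric(length(cohort$subjects)))
  vapply(cohort$subjects, function(s) {
    if (length(s$w) != length(params$gamma))
      stop("subject ", s$subject_id, ": covariate length does not match gamma")
    sum(params$gamma * s$w)
  }, numeric(1))
}

#' Joint log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Evaluates the marginal log-likelihood of the joint growth/rupture model,
#' integrating the subject-level random effects out of the product of the
#' longitudinal Gaussian density, the event likelihood
#' `h(T)^delta * S(T)`, and the random-effects prior. The integral is
#' evaluated per subject by Gauss-Hermite quadrature centred at the
#' subject's conditional mode and rescaled by the curvature there
#' (pseudo-adaptive quadrature); the inner cumulative hazard uses
#' Gauss-Legendre quadrature on `(0, T_i)`.
#'
#' @param cohort An [aaa_cohort()].
#' @param params An [jm_params()] object.
#' @param gh Gauss-Hermite nodes per random-effect dimension (default 9).
#' @param gl Gauss-Legendre nodes for the cumulative hazard (default 15).
#' @param details If `TRUE`, also return per-subject contributions and the
#'   empirical Bayes modes/curvatures.
#' @return The log-likelihood (scalar), or a list when `details = TRUE`.
#' @export
joint_loglik <- function(cohort, params, gh = 9, gl = 15, details = FALSE) {
  stopifnot(inherits(cohort, "aaa_cohort"), inherits(params, "aaa_jm_params"))
  flat <- .cohort_flat(cohort)
  if (any(flat$ni < 1)) stop("every subject needs at least one measurement")
  ghr <- .gh_rule(gh)
  glr <- .gl_rule(gl)
  res <- cpp_joint_loglik(flat$y, flat$t, flat$ni, flat$Tobs, flat$delta,
                          .gamma_offsets(cohort, params),
                          params$spec$degree, params$spec$q,
                          .assoc_code(params$assoc$kind),
                          if (params$baseline$kind == "exponential") 0L else 1L,
                          params$beta, params$sigma_eps, params$Sigma,
                          params$assoc$alpha, .baseline_vec(params),
                          ghr$x, ghr$w, glr$x, glr$w, details)
  if (!all(is.finite(res$per_subject))) {
    bad <- cohort$survival$subject_id[!is.finite(res$per_subject)]
    stop("non-finite likelihood contribution for subject(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (details) {
    res$subject_id <- cohort$survival$subject_id
    res
  } else {
    res$loglik
  }
}
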