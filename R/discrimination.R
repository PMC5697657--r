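# Time-dependent discrimination. At a landmark t and window dt, the model
# is asked to rank subjects at risk at t by their predicted conditional
# rupture probability F(t + dt | t); concordance is counted over pairs of
# one subject rupturing within the window and one surviving beyond it.

# predicted window risk for each at-risk subject; n_mc = 0 uses the
# conditional-mode plug-in (deterministic), otherwise a Monte-Carlo mean
.window_risks <- function(fit, cohort, t, dt, n_mc = 0, seed = NULL,
                          gl = 7, subjects_idx = NULL) {
  if (is.null(subjects_idx)) subjects_idx <- seq_along(cohort$subjects)
  if (!is.null(seed)) set.seed(seed)
  vapply(subjects_idx, function(i) {
    s <- cohort$subjects[[i]]
    if (n_mc == 0) {
      post <- .subject_logpost(fit$params, s, t, gl = 15)
      H <- cum_hazard(fit$params, post$mode, t, t + dt, w = s$w, gl = gl)
      1 - exp(-H)
    } else {
      d <- posterior_b_draws(fit, s, t, n = n_mc, theta_uncertainty = FALSE)
      mean(vapply(seq_len(n_mc), function(k)
        1 - exp(-cum_hazard(d$params[[k]], d$b[k, ], t, t + dt,
                            w = s$w, gl = gl)), numeric(1)))
    }
  }, numeric(1))
}

#' Dynamic AUC at a landmark time
#'
#' Concordance of the predicted conditional rupture probability
#' `F(t + dt | t)` among comparable pairs: one subject rupturing within
#' `(t, t + dt]` (case) and one surviving event-free beyond `t + dt`
#' (control). Subjects censored inside the window are not comparable and
#' are excluded (no censoring weights). Ties in the predictions count 1/2.
#'
#' @param fit An `aaa_jm_fit`.
#' @param cohort An [aaa_cohort()].
#' @param t Landmark time (years); only measurements up to `t` inform the
#'   predictions.
#' @param dt Prediction window (years).
#' @param n_mc Monte-Carlo draws per subject for the predicted risk; 0
#'   (default) uses the conditional-mode plug-in.
#' @param seed Optional RNG seed (only used when `n_mc > 0`).
#' @return The AUC in `[0, 1]`, or `NA` (with a warning) when there are no
#'   comparable pairs. Attributes `"n_cases"` and `"n_controls"` report the
#'   pair counts.
#' @export
dynamic_auc <- function(fit, cohort, t, dt, n_mc = 0, seed = NULL) {
  stopifnot(inherits(cohort, "aaa_cohort"), dt > 0)
  sv <- cohort$survival
  at_risk <- sv$obs_time_years > t
  case <- at_risk & sv$event == 1 & sv$obs_time_years <= t + dt
  ctrl <- sv$obs_time_years > t + dt
  if (!any(case) || !any(ctrl)) {
    warning("no comparable pairs at landmark t = ", t)
    return(structure(NA_real_, n_cases = sum(case), n_controls = sum(ctrl)))
  }
  idx <- which(case | ctrl)
  r <- .window_risks(fit, cohort, t, dt, n_mc = n_mc, seed = seed,
                     subjects_idx = idx)
  is_case <- case[idx]
  rc <- r[is_case]
  rn <- r[!is_case]
  cmp <- outer(rc, rn, function(a, b) (a > b) + 0.5 * (a == b))
  structure(mean(cmp), n_cases = length(rc), n_controls = length(rn))
}

#' Dynamic discrimination index (events-weighted landmark AUC)
#'
#' An omnibus summary of time-dependent discrimination: the average of
#' landmark-specific dynamic AUCs weighted by the number of rupture events
#' falling in each landmark's prediction window. Landmarks without
#' comparable pairs are dropped (with a warning) and the weights
#' renormalised.
#'
#' @inheritParams dynamic_auc
#' @param landmarks Landmark times in years (default yearly over the
#'   observed follow-up, starting at 1).
#' @return An object of class `aaa_ddi` with per-landmark AUCs, weights and
#'   the weighted summary.
#' @export
ddi <- function(fit, cohort, dt = 2, landmarks = NULL, n_mc = 0,
                seed = NULL) {
  if (is.null(landmarks)) {
    tmax <- max(cohort$survival$obs_time_years)
    landmarks <- seq(1, max(1, floor(tmax - dt)), by = 1)
  }
  if (!length(landmarks)) stop("no landmarks")
  auc <- numeric(length(landmarks))
  ev <- numeric(length(landmarks))
  for (j in seq_along(landmarks)) {
    tj <- landmarks[j]
    a <- suppressWarnings(dynamic_auc(fit, cohort, tj, dt, n_mc = n_mc,
                                      seed = seed))
    auc[j] <- as.numeric(a)
    sv <- cohort$survival
    ev[j] <- sum(sv$event == 1 & sv$obs_time_years > tj &
                   sv$obs_time_years <= tj + dt)
  }
  ok <- is.finite(auc) & ev > 0
  if (!any(ok)) stop("no landmark has comparable pairs")
  if (!all(ok)) warning(sum(!ok), " landmark(s) without comparable pairs dropped")
  w <- ifelse(ok, ev, 0)
  w <- w / sum(w)
  structure(list(landmarks = landmarks, dt = dt, auc = auc, weights = w,
                 events = ev, summary = sum(w[ok] * auc[ok])),
            class = "aaa_ddi")
}

#' @export
print.aaa_ddi <- function(x, ...) {
  cat(sprintf("Dynamic discrimination (window %.1f y): weighted AUC = %.3f\n",
              x$dt, x$summary))
  print(data.frame(landmark = x$landmarks, auc = round(x$auc, 3),
                   events = x$events, weight = round(x$weights, 3)))
  invisible(x)
}
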