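# CSV and structured-text artefacts. All CSVs are comma-separated UTF-8
# with a mandatory header; '#' lines are comments (used for seed/config
# provenance headers).

.fnv1a <- function(x) {
  # tiny stable content hash for artefact headers
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_csv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (l in header_lines) writeLines(paste0("# ", l), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a cohort from longitudinal and survival CSV files
#'
#' Expects the schemas: longitudinal `subject_id, time_years, diameter_mm`;
#' survival `subject_id, baseline_age_years, obs_time_years, event`.
#' Validation (matching subjects, sorted times, unit heuristics) is done by
#' [aaa_cohort()].
#'
#' @param long_path,surv_path File paths.
#' @return An [aaa_cohort()].
#' @export
read_cohort <- function(long_path, surv_path) {
  aaa_cohort(.read_csv(long_path), .read_csv(surv_path))
}

#' Write a cohort to a pair of CSV files
#'
#' @param cohort An [aaa_cohort()].
#' @param prefix Output path prefix; writes `<prefix>_long.csv` and
#'   `<prefix>_surv.csv`.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  hdr <- c(paste0("seed: ", cohort$seed %||% "NA"),
           paste0("config: ", .fnv1a(cohort$design %||% "none")))
  p1 <- paste0(prefix, "_long.csv")
  p2 <- paste0(prefix, "_surv.csv")
  .write_csv(cohort$longitudinal, p1, hdr)
  .write_csv(cohort$survival, p2, hdr)
  invisible(c(p1, p2))
}

#' Read a life table from CSV
#'
#' Expects columns `age` and `annual_death_prob`.
#'
#' @param path File path.
#' @return An [life_table()].
#' @export
read_life_table <- function(path) {
  df <- .read_csv(path)
  if (!all(c("age", "annual_death_prob") %in% names(df)))
    stop("life table needs columns: age, annual_death_prob")
  life_table(df$age, df$annual_death_prob)
}

#' Write a life table to CSV
#' @param table An [life_table()].
#' @param path Output path.
#' @export
write_life_table <- function(table, path) {
  .write_csv(data.frame(age = table$ages, annual_death_prob = table$q), path)
}

#' Serialise a fitted joint model to JSON
#'
#' Stores the natural-scale estimates (names `beta0, beta1, beta2, log_h0,
#' alpha1, alpha2, sigma0, sigma1, rho, sigma_eps`, as applicable),
#' standard errors, the unconstrained-scale parameter vector and its
#' covariance, and the model structure, so the fit can be reloaded for
#' prediction without the data.
#'
#' @param fit An `aaa_jm_fit`.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    package = "aaadecide", format = 1L,
    structure = list(degree = fit$params$spec$degree,
                     random = fit$params$spec$random,
                     assoc_kind = fit$params$assoc$kind,
                     baseline_kind = fit$params$baseline$kind,
                     n_gamma = length(fit$params$gamma)),
    estimates = as.list(fit$estimates), se = as.list(fit$se),
    phi = as.list(fit$phi), free = fit$free,
    vcov_phi = fit$vcov_phi, vcov = fit$vcov,
    log_lik = fit$log_lik, aic = fit$aic, npar = fit$npar,
    converged = fit$converged, n = fit$n, n_events = fit$n_events,
    gh = fit$gh, gl = fit$gl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Reload a fitted joint model from JSON
#'
#' @param path Path written by [write_fit()].
#' @return An `aaa_jm_fit` (without per-subject empirical Bayes output).
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- obj$structure
  spec <- trajectory_spec(st$degree, st$random)
  tpl <- .phi_template(spec, st$assoc_kind, st$baseline_kind, st$n_gamma)
  num_vec <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  phi <- num_vec(obj$phi)
  params <- .phi_to_params(phi, tpl)
  vphi <- obj$vcov_phi
  if (!is.null(vphi)) {
    if (is.list(vphi)) vphi <- do.call(rbind, lapply(vphi, num_vec))
    vphi <- as.matrix(vphi)
  }
  structure(list(params = params,
                 estimates = num_vec(obj$estimates),
                 se = num_vec(obj$se),
                 vcov = NULL, vcov_phi = vphi, phi = phi,
                 free = obj$free, template = tpl,
                 log_lik = obj$log_lik %||% NA_real_,
                 aic = obj$aic %||% NA_real_, npar = obj$npar,
                 converged = obj$converged, optim = NULL, eb = NULL,
                 n = obj$n %||% NA_integer_,
                 n_events = obj$n_events %||% NA_integer_,
                 gh = obj$gh, gl = obj$gl, call = NULL),
            class = "aaa_jm_fit")
}

#' Export a conditional risk curve to CSV
#' @param curve An `aaa_risk_curve`.
#' @param path Output path.
#' @export
write_risk_curve <- function(curve, path) {
  .write_csv(data.frame(u_years = curve$grid_u, mean = curve$mean_risk,
                        lower = curve$lower, upper = curve$upper),
             path, c(paste0("subject: ", curve$subject_id),
                     paste0("t: ", curve$t),
                     paste0("n_mc: ", curve$n_mc),
                     paste0("seed: ", curve$seed %||% "NA")))
}

#' Export a decision result to CSV
#'
#' Writes the expected life-years curve with a summary header block
#' (optimal time, percentile interval, diameter at the optimum, CV).
#'
#' @param decision An `aaa_decision`.
#' @param path Output path.
#' @export
write_decision <- function(decision, path) {
  hdr <- c(sprintf("tx_opt: %.6g", decision$tx_opt),
           sprintf("interval: %.6g %.6g", decision$interval[1],
                   decision$interval[2]),
           sprintf("diameter_at_opt_mm: %.6g", decision$diameter_at_opt),
           sprintf("cv: %.6g", decision$cv),
           sprintf("n_mc: %d", decision$n_mc),
           sprintf("seed: %s", decision$seed %||% "NA"))
  .write_csv(data.frame(tx_years = decision$grid_tx,
                        expected_life_years = decision$expected_life_years),
             path, hdr)
}

#' Pipeline configuration
#'
#' Bundles the settings shared across the simulate / fit / predict / decide
#' stages. All randomness in [run_pipeline()] flows from `seed`.
#'
#' @param seed Integer RNG seed.
#' @param n_subjects Cohort size for the simulation stage.
#' @param gh,gl Quadrature orders (see [joint_loglik()]).
#' @param grid_step Decision grid spacing in years (default 0.25).
#' @param horizon_age Decision horizon age (default 105).
#' @param n_mc Monte-Carlo iterations for prediction/decision (default
#'   1000).
#' @param ely_variant `"literal"` or `"aaa_weighted"`; see
#'   [optimal_intervention()].
#' @param model Operative-risk model, 1 or 2.
#' @param out_dir Output directory for artefacts.
#' @return An object of class `aaa_run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 200, gh = 9, gl = 15,
                       grid_step = 0.25, horizon_age = 105, n_mc = 1000,
                       ely_variant = "literal", model = 2,
                       out_dir = tempfile("aaadecide_run_")) {
  stopifnot(gh >= 1, gl >= 1, grid_step > 0, horizon_age > 66, n_mc >= 1)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects, gh = gh,
                 gl = gl, grid_step = grid_step, horizon_age = horizon_age,
                 n_mc = n_mc, ely_variant = ely_variant, model = model,
                 out_dir = out_dir),
            class = "aaa_run_config")
}

#' Run the full simulate / fit / predict / decide pipeline
#'
#' End-to-end demonstration run on a synthetic cohort: simulates a cohort
#' at the canonical growth/rupture parameters, fits the joint model,
#' produces a conditional risk curve and an optimal-intervention decision
#' for the first still-at-risk subject, and writes every artefact (CSV and
#' JSON, each with a seed/config header) to `config$out_dir`. Deterministic
#' given the config.
#'
#' @param config An [run_config()].
#' @param params Generating parameters (default [aaa_growth_params()]).
#' @param lifetable Life table (default [gompertz_life_table()]).
#' @return Invisibly, a list with the cohort, fit, risk curve, decision and
#'   artefact paths.
#' @export
run_pipeline <- function(config = run_config(),
                         params = aaa_growth_params(),
                         lifetable = gompertz_life_table()) {
  stopifnot(inherits(config, "aaa_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(x) file.path(config$out_dir, x)

  cohort <- simulate_cohort(params, cohort_design(config$n_subjects),
                            lifetable, seed = config$seed)
  write_cohort(cohort, pth("cohort"))
  fit <- fit_joint_model(cohort, gh = config$gh, gl = config$gl)
  write_fit(fit, pth("fit.json"))

  sv <- cohort$survival
  cand <- which(sv$event == 0 & sv$obs_time_years >= 1)
  i <- if (length(cand)) cand[1] else 1L
  subj <- cohort$subjects[[i]]
  t <- max(subj$times)
  age_t <- subj$baseline_age + t
  grid <- seq(t, t + min(10, config$horizon_age - age_t - 0.5),
              by = config$grid_step)
  risk <- conditional_rupture_prob(fit, subj, t, grid, n_mc = config$n_mc,
                                   seed = config$seed + 1L)
  write_risk_curve(risk, pth("risk_curve.csv"))
  dec <- optimal_intervention(fit, subj, lifetable,
                              operative_risk(model = config$model),
                              t = t, grid_step = config$grid_step,
                              horizon_age = config$horizon_age,
                              n_mc = config$n_mc, seed = config$seed + 2L,
                              ely_variant = config$ely_variant)
  write_decision(dec, pth("decision.csv"))

  invisible(list(cohort = cohort, fit = fit, risk_curve = risk,
                 decision = dec, subject = subj,
                 paths = c(cohort_long = pth("cohort_long.csv"),
                           cohort_surv = pth("cohort_surv.csv"),
                           fit = pth("fit.json"),
                           risk_curve = pth("risk_curve.csv"),
                           decision = pth("decision.csv"))))
}
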