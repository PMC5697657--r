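#' A single subject's surveillance history
#'
#' Bundles one subject's ultrasound measurement history together with their
#' survival status, for use by the dynamic prediction and decision
#' functions.
#'
#' @param subject_id Identifier (scalar).
#' @param baseline_age Age in years at study entry.
#' @param times Measurement times in years since entry (nondecreasing,
#'   >= 0).
#' @param diameters Measured AAA diameters in mm, same length as `times`.
#' @param event_time Observed event/censoring time in years (defaults to
#'   the last measurement time).
#' @param event Event indicator: 1 = rupture observed, 0 = censored.
#' @param w Baseline covariate vector entering the hazard via `gamma`
#'   (default none).
#' @return An object of class `aaa_subject`.
#' @export
#' @examples
#' subject_history("s1", baseline_age = 65, times = 0, diameters = 45)
subject_history <- function(subject_id, baseline_age, times, diameters,
                            event_time = NULL, event = 0, w = numeric(0)) {
  times <- as.numeric(times); diameters <- as.numeric(diameters)
  if (length(times) != length(diameters))
    stop("times and diameters must have equal length")
  if (length(times) && (any(times < 0) || is.unsorted(times)))
    stop("times must be nondecreasing and >= 0")
  if (is.null(event_time))
    event_time <- if (length(times)) max(times) else 0
  if (length(times) && event_time < max(times))
    stop("event_time precedes the last measurement")
  if (!event %in% c(0, 1)) stop("event must be 0 or 1")
  structure(list(subject_id = subject_id,
                 baseline_age = as.numeric(baseline_age),
                 times = times, diameters = diameters,
                 event_time = as.numeric(event_time),
                 event = as.integer(event), w = as.numeric(w)),
            class = "aaa_subject")
}

#' @export
print.aaa_subject <- function(x, ...) {
  cat(sprintf("Subject %s: age %.1f at entry, %d measurement(s), %s at t = %.2f y\n",
              as.character(x$subject_id), x$baseline_age, length(x$times),
              if (x$event == 1) "rupture" else "censored", x$event_time))
  invisible(x)
}

#' Assemble a cohort dataset from longitudinal and survival tables
#'
#' Validates and pairs the two tables that define a surveillance cohort.
#' Every subject must appear in both; measurement times are sorted if
#' needed (with a message) and must not exceed the subject's observed
#' event/censoring time.
#'
#' @param longitudinal Data frame with columns `subject_id`, `time_years`,
#'   `diameter_mm`.
#' @param survival Data frame with columns `subject_id`,
#'   `baseline_age_years`, `obs_time_years`, `event`.
#' @return An object of class `aaa_cohort`: the validated tables plus a
#'   precomputed per-subject list.
#' @export
aaa_cohort <- function(longitudinal, survival) {
  need_l <- c("subject_id", "time_years", "diameter_mm")
  need_s <- c("subject_id", "baseline_age_years", "obs_time_years", "event")
  if (!all(need_l %in% names(longitudinal)))
    stop("longitudinal table needs columns: ", paste(need_l, collapse = ", "))
  if (!all(need_s %in% names(survival)))
    stop("survival table needs columns: ", paste(need_s, collapse = ", "))
  for (cc in need_l[-1]) if (!is.numeric(longitudinal[[cc]]))
    stop("non-numeric values in longitudinal column ", cc)
  for (cc in need_s[-1]) if (!is.numeric(survival[[cc]]))
    stop("non-numeric values in survival column ", cc)
  if (anyDuplicated(survival$subject_id))
    stop("duplicated subject_id in survival table")
  lid <- unique(longitudinal$subject_id)
  sid <- survival$subject_id
  if (length(miss <- setdiff(lid, sid)))
    stop("subjects in longitudinal but not survival table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(miss <- setdiff(sid, lid)))
    stop("subjects in survival but not longitudinal table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1")

  o <- order(match(longitudinal$subject_id, sid), longitudinal$time_years)
  if (is.unsorted(o)) {
    message("longitudinal records reordered by subject and time")
    longitudinal <- longitudinal[o, , drop = FALSE]
  }
  # unit sanity heuristics: diameters in mm, times in years
  if (mean(longitudinal$diameter_mm < 15, na.rm = TRUE) > 0.5)
    warning("most diameters < 15: are diameters in cm rather than mm?")
  if (any(longitudinal$time_years < 0) || any(survival$obs_time_years < 0))
    stop("negative times")

  idx <- split(seq_len(nrow(longitudinal)), match(longitudinal$subject_id, sid))
  subjects <- vector("list", length(sid))
  for (i in seq_along(sid)) {
    rows <- idx[[as.character(i)]]
    ti <- longitudinal$time_years[rows]
    if (max(ti) > survival$obs_time_years[i] + 1e-9)
      stop("subject ", sid[i], " has measurements after its observed time")
    subjects[[i]] <- subject_history(sid[i], survival$baseline_age_years[i],
                                     ti, longitudinal$diameter_mm[rows],
                                     event_time = survival$obs_time_years[i],
                                     event = survival$event[i])
  }
  structure(list(longitudinal = longitudinal, survival = survival,
                 subjects = subjects),
            class = "aaa_cohort")
}

#' @export
print.aaa_cohort <- function(x, ...) {
  py <- sum(x$survival$obs_time_years)
  cat(sprintf("AAA surveillance cohort: %d subjects, %d measurements, %d rupture(s) in %.0f person-years\n",
              nrow(x$survival), nrow(x$longitudinal),
              sum(x$survival$event), py))
  invisible(x)
}

# flat representation consumed by the C++ likelihood
.cohort_flat <- function(cohort) {
  subs <- cohort$subjects
  list(y = unlist(lapply(subs, `[[`, "diameters")),
       t = unlist(lapply(subs, `[[`, "times")),
       ni = vapply(subs, function(s) length(s$times), integer(1)),
       Tobs = vapply(subs, `[[`, numeric(1), "event_time"),
       delta = vapply(subs, `[[`, integer(1), "event"))
}
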