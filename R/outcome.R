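#' Volume-load of a training session
#'
#' Volume-load is the product of the load lifted and the total number of
#' repetitions across sets, in kg x reps. It is the package's proxy for
#' training progression: a change in load, sets or repetitions all move it.
#'
#' @param load_kg positive load in kg (scalar or vector).
#' @param reps repetitions per set: a numeric vector for one session, or a
#'   list of such vectors matching `load_kg`.
#' @return volume-load(s) in kg x reps.
#' @examples
#' compute_volume_load(50, c(12, 12, 12))  # 1800
#' @export
compute_volume_load <- function(load_kg, reps) {
  if (!is.list(reps)) reps <- list(reps)
  vl_assert(length(load_kg) == length(reps) || length(load_kg) == 1L,
            "load_kg and reps lengths differ")
  totals <- vapply(reps, function(r) {
    vl_assert(length(r) > 0, "session has zero sets")
    vl_assert(all(is.finite(r)) && all(r >= 0), "repetitions must be non-negative")
    sum(r)
  }, numeric(1))
  vl_assert(all(load_kg > 0), "load_kg must be positive")
  unname(load_kg * totals)
}

# parse "12;12;12" -> integer vector
parse_reps <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(r) as.numeric(r))
}

#' Session-validity rule
#'
#' A session counts as valid when more than two sets were performed and more
#' than eight repetitions were achieved. Under the default `"mean"` reading,
#' the repetition condition applies to the mean repetitions per set (matching
#' a 3 x 12 prescription); `"total"` applies it to the summed repetitions.
#'
#' @param n_sets number of sets (scalar or vector).
#' @param reps repetitions per set: numeric vector or list of vectors.
#' @param rule `"mean"` (default) or `"total"`.
#' @return logical vector.
#' @examples
#' is_valid_session(3, c(9, 9, 9))   # TRUE
#' is_valid_session(2, c(12, 12))    # FALSE: not more than two sets
#' is_valid_session(3, c(8, 8, 8))   # FALSE: mean reps not above eight
#' @export
is_valid_session <- function(n_sets, reps, rule = c("mean", "total")) {
  rule <- match.arg(rule)
  if (!is.list(reps)) reps <- list(reps)
  rep_stat <- vapply(reps, function(r) {
    if (rule == "mean") mean(r) else sum(r)
  }, numeric(1))
  n_sets > 2 & rep_stat > 8
}

#' Remove familiarization sessions
#'
#' Drops each patient's first two chronological sessions (all exercises
#' performed in them) as technique-familiarization, and indexes the remaining
#' sessions per patient as `t = 0, 1, 2, ...` in attended order. Patients
#' with fewer than three sessions carry no analyzable data and are removed
#' with a warning.
#'
#' @param log a training-log tibble with columns `patient_id`,
#'   `exercise_id`, `session_index` (and any others, which are preserved).
#' @return the log restricted to post-familiarization sessions, with an
#'   added column `t`.
#' @export
drop_familiarization <- function(log) {
  if (nrow(log) == 0) {
    out <- log
    out$t <- integer(0)
    return(out)
  }
  counts <- tapply(log$session_index, log$patient_id,
                   function(s) length(unique(s)))
  too_few <- names(counts)[counts < 3]
  if (length(too_few) > 0) {
    warning(sprintf(
      "dropping %d patient(s) with fewer than 3 sessions: %s",
      length(too_few), paste(too_few, collapse = ", ")
    ), call. = FALSE)
    log <- log[!(log$patient_id %in% too_few), , drop = FALSE]
  }
  if (nrow(log) == 0) {
    out <- log
    out$t <- integer(0)
    return(out)
  }
  out <- dplyr::group_by(log, .data$patient_id)
  out <- dplyr::mutate(out, .rank = dplyr::dense_rank(.data$session_index))
  out <- dplyr::ungroup(out)
  out <- out[out$.rank > 2, , drop = FALSE]
  out$t <- out$.rank - 3L
  out$.rank <- NULL
  out
}

#' Equalize repetition overshoots
#'
#' When a session's repetitions exceed the 12-rep prescription, its
#' volume-load overstates the planned dose; such sessions get the volume-load
#' of the next chronologically later valid session instead. An overshoot in
#' the final session, with no later valid session to borrow from, is capped
#' at the 12-rep equivalent `load_kg * n_sets * 12`.
#'
#' The series is processed from the last session backwards, so a run of
#' consecutive overshoots resolves to the first non-overshot value after it.
#'
#' @param series a tibble of one patient x exercise, chronologically ordered,
#'   with columns `load_kg`, `n_sets`, `reps` and `vl` (invalid sessions
#'   already removed).
#' @return the series with `vl` adjusted; row count never changes.
#' @export
equalize_overshoot <- function(series) {
  if (nrow(series) == 0) return(series)
  reps <- parse_reps(series$reps)
  max_rep <- vapply(reps, max, numeric(1))
  over <- max_rep > 12
  if (!any(over)) return(series)
  vl <- series$vl
  for (i in rev(seq_along(vl))) {
    if (!over[i]) next
    if (i < length(vl)) {
      vl[i] <- vl[i + 1]  # already resolved by the backward pass
    } else {
      vl[i] <- series$load_kg[i] * series$n_sets[i] * 12
    }
  }
  series$vl <- vl
  series
}

#' Per-exercise baseline statistics
#'
#' For each exercise, the baseline distribution is formed by each patient's
#' first valid post-familiarization session volume-load; its mean and sample
#' SD (n - 1 denominator) define the standardization anchors.
#'
#' @param log a tibble with columns `patient_id`, `exercise_id`, `t`, `vl`
#'   (familiarization removed, validity filter applied).
#' @return a tibble with columns `exercise_id`, `mean_vl`, `sd_vl`, `n`.
#' @export
baseline_stats <- function(log) {
  vl_assert(nrow(log) > 0, "empty log: no baseline to compute")
  first <- dplyr::slice_min(
    dplyr::group_by(log, .data$patient_id, .data$exercise_id),
    .data$t, n = 1, with_ties = FALSE
  )
  first <- dplyr::ungroup(first)
  out <- dplyr::summarise(
    dplyr::group_by(first, .data$exercise_id),
    mean_vl = mean(.data$vl),
    sd_vl = stats::sd(.data$vl),
    n = dplyr::n(),
    .groups = "drop"
  )
  bad <- out$n < 2 | !is.finite(out$sd_vl) | out$sd_vl <= 0
  if (any(bad)) {
    stop(sprintf(
      "baseline standardization undefined for exercise(s): %s (need >= 2 patients and SD > 0)",
      paste(out$exercise_id[bad], collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Standardize volume-loads to baseline
#'
#' Computes `z = (vl - mean_vl) / sd_vl` per exercise, so every coefficient
#' downstream is in baseline-SD (SMD) units of that exercise.
#'
#' @param log a tibble with columns `patient_id`, `exercise_id`, `t`, `vl`.
#' @param stats a [baseline_stats()] table covering every exercise in `log`.
#' @return a tibble of standardized observations: `patient_id`,
#'   `exercise_id`, `t`, `z`, `vl_raw`.
#' @export
standardize <- function(log, stats) {
  missing <- setdiff(unique(log$exercise_id), stats$exercise_id)
  vl_assert(length(missing) == 0,
            "no baseline statistics for exercise(s): %s",
            paste(missing, collapse = ", "))
  out <- dplyr::left_join(log, stats, by = "exercise_id")
  tibble::tibble(
    patient_id = out$patient_id,
    exercise_id = out$exercise_id,
    t = out$t,
    z = (out$vl - out$mean_vl) / out$sd_vl,
    vl_raw = out$vl
  )
}

#' Filter patients by attendance
#'
#' Retains patients whose attended-session count reaches at least
#' `fraction * n_scheduled` sessions. Counts are taken from the log: the
#' number of distinct `session_index` values if present, otherwise the
#' number of distinct `t` values plus two (the familiarization sessions a
#' standardized table no longer carries). A per-patient count table can be
#' supplied instead when attendance is known externally.
#'
#' @param log a training-log or standardized-observation tibble.
#' @param fraction required attendance fraction in (0, 1].
#' @param n_scheduled maximum number of scheduled sessions (default 24).
#' @param counts optional tibble with columns `patient_id`, `n_attended`.
#' @return the log restricted to retained patients.
#' @export
filter_attendance <- function(log, fraction, n_scheduled = 24, counts = NULL) {
  vl_assert(is.numeric(fraction) && fraction > 0 && fraction <= 1,
            "fraction must be in (0, 1]")
  if (nrow(log) == 0) return(log)
  if (is.null(counts)) {
    if ("session_index" %in% names(log)) {
      n_att <- tapply(log$session_index, log$patient_id,
                      function(s) length(unique(s)))
    } else {
      n_att <- tapply(log$t, log$patient_id,
                      function(s) length(unique(s)) + 2)
    }
    counts <- tibble::tibble(patient_id = names(n_att),
                             n_attended = as.integer(n_att))
  }
  keep <- counts$patient_id[counts$n_attended >= fraction * n_scheduled]
  log[log$patient_id %in% keep, , drop = FALSE]
}

#' Construct the standardized volume-load outcome from a raw log
#'
#' Runs the full outcome pipeline: familiarization removal, session-validity
#' filtering, volume-load computation, repetition-overshoot equalization,
#' per-exercise baseline statistics, z-standardization, and (optionally)
#' within-series outlier removal.
#'
#' @param log a raw training-log tibble (`patient_id`, `exercise_id`,
#'   `session_index`, `load_kg`, `n_sets`, `reps`).
#' @param validity_rule repetition reading for [is_valid_session()].
#' @param outlier_z remove observations with `|z| >` this value within each
#'   patient x exercise series, after standardization; `NULL` disables the
#'   rule. Default 4.
#' @param baseline optional pre-computed [baseline_stats()] table; when
#'   supplied (e.g. generator-truth anchors in a round-trip check) it is used
#'   instead of the empirical baseline.
#' @return an object of class `vl_outcome`: a list with `observations`
#'   (standardized tibble), `baseline` (the anchors used) and `removed`
#'   (named counts of rows removed by each filter).
#' @export
construct_outcome <- function(log, validity_rule = c("mean", "total"),
                              outlier_z = 4, baseline = NULL) {
  validity_rule <- match.arg(validity_rule)
  removed <- c(familiarization = 0L, invalid = 0L, equalized = 0L, outlier = 0L)

  n0 <- nrow(log)
  log <- drop_familiarization(log)
  removed["familiarization"] <- n0 - nrow(log)

  reps <- parse_reps(log$reps)
  valid <- is_valid_session(log$n_sets, reps, rule = validity_rule)
  removed["invalid"] <- sum(!valid)
  log <- log[valid, , drop = FALSE]
  vl_assert(nrow(log) > 0, "no valid sessions remain")

  log$vl <- compute_volume_load(log$load_kg, parse_reps(log$reps))

  log <- dplyr::arrange(log, .data$patient_id, .data$exercise_id, .data$t)
  pre <- log$vl
  log <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(log, .data$patient_id, .data$exercise_id),
    function(df, key) equalize_overshoot(df)
  ))
  removed["equalized"] <- sum(log$vl != pre)

  if (is.null(baseline)) baseline <- baseline_stats(log)
  obs <- standardize(log, baseline)

  if (!is.null(outlier_z)) {
    out_flag <- abs(obs$z) > outlier_z
    removed["outlier"] <- sum(out_flag)
    obs <- obs[!out_flag, , drop = FALSE]
  }

  structure(
    list(observations = obs, baseline = baseline, removed = removed,
         validity_rule = validity_rule),
    class = "vl_outcome"
  )
}
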