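#' Configuration for the synthetic training-log generator
#'
#' Defines a synthetic resistance-training cohort: population trajectory
#' coefficients on the standardized (SMD) scale, variance components at the
#' exercise, patient and patient-by-exercise levels, session-to-session
#' residual noise, attendance, and the raw-scale anchors used to invert
#' standardized volume-loads back into kilogram loads.
#'
#' The defaults describe a cohort of 69 breast-cancer patients training on
#' eight machine exercises over 24 scheduled sessions (two familiarization
#' sessions plus 22 analysis sessions), with population coefficients and
#' between-exercise / between-patient dispersion set to the posterior means
#' of the fitted three-level growth model this package implements. The
#' patient-by-exercise dispersion and the residual SD are not identified by
#' those summaries alone; their defaults are chosen so that the within-patient
#' spread of exercise slopes is about 0.12 SMD, a realistic figure for
#' supervised machine training in this population.
#'
#' @param n_patients number of patients (>= 2).
#' @param exercise_names character vector of exercise labels.
#' @param n_sessions number of scheduled analysis sessions (>= 3). Raw logs
#'   additionally contain two leading familiarization sessions per patient.
#' @param population_beta length-3 numeric: intercept, linear and quadratic
#'   population coefficients (SMD, SMD/TS, SMD/TS^2).
#' @param sd_exercise,sd_patient,sd_patient_exercise length-3 non-negative
#'   numerics: SDs of the intercept/linear/quadratic group effects at each
#'   level.
#' @param corr_exercise,corr_patient,corr_patient_exercise 3x3 correlation
#'   matrices among the intercept/linear/quadratic effects within a level
#'   (default identity).
#' @param residual_sd positive session-level noise SD (SMD).
#' @param attendance_rate probability that a scheduled analysis session is
#'   attended (independent Bernoulli per patient x session). The default 0.49
#'   makes roughly half the cohort meet a 50%-of-24-sessions attendance
#'   criterion.
#' @param overshoot_rate probability that an attended session's repetitions
#'   overshoot the 12-rep prescription (13-15 reps per set).
#' @param invalid_rate probability that an attended session fails the
#'   session-validity rule (fewer than three sets, or eight or fewer mean
#'   repetitions).
#' @param baseline_load_mean,baseline_load_sd raw-scale anchors (kg) mapping
#'   standardized volume-load back to machine loads; `baseline_load_sd` must
#'   be positive for raw-log generation.
#' @param seed integer seed; a fixed seed yields bit-identical output.
#' @return an object of class `vl_generator_config`.
#' @export
generator_config <- function(n_patients = 69,
                             exercise_names = c(
                               "leg_press", "leg_extension", "leg_curl",
                               "internal_rotation", "external_rotation",
                               "rowing", "lat_pulldown", "butterfly"
                             ),
                             n_sessions = 24,
                             population_beta = c(0.049, 0.093, -0.002),
                             sd_exercise = c(0.047, 0.043, 0.002),
                             sd_patient = c(1.007, 0.155, 0.008),
                             sd_patient_exercise = c(0.30, 0.113, 0.003),
                             corr_exercise = diag(3),
                             corr_patient = diag(3),
                             corr_patient_exercise = diag(3),
                             residual_sd = 0.25,
                             attendance_rate = 0.49,
                             overshoot_rate = 0.05,
                             invalid_rate = 0.05,
                             baseline_load_mean = 40,
                             baseline_load_sd = 6,
                             seed = 20240L) {
  vl_assert(is_count(n_patients, min = 2L), "n_patients must be an integer >= 2")
  vl_assert(is.character(exercise_names) && length(exercise_names) >= 1 &&
              !anyDuplicated(exercise_names),
            "exercise_names must be a non-empty set of unique labels")
  vl_assert(is_count(n_sessions, min = 3L), "n_sessions must be an integer >= 3")
  vl_assert(is.numeric(population_beta) && length(population_beta) == 3L &&
              all(is.finite(population_beta)),
            "population_beta must be three finite coefficients")
  for (nm in c("sd_exercise", "sd_patient", "sd_patient_exercise")) {
    vl_assert(is_sd_triple(get(nm)), "%s must be three non-negative SDs", nm)
  }
  for (nm in c("corr_exercise", "corr_patient", "corr_patient_exercise")) {
    m <- get(nm)
    vl_assert(is.matrix(m) && all(dim(m) == 3) && isSymmetric(unname(m)) &&
                all(abs(diag(m) - 1) < 1e-12) &&
                min(eigen(m, only.values = TRUE)$values) > -1e-8,
              "%s must be a 3x3 correlation matrix", nm)
  }
  vl_assert(is.numeric(residual_sd) && length(residual_sd) == 1L &&
              is.finite(residual_sd) && residual_sd > 0,
            "residual_sd must be a single positive number")
  for (nm in c("attendance_rate", "overshoot_rate", "invalid_rate")) {
    vl_assert(is_prob(get(nm)), "%s must be a probability in [0, 1]", nm)
  }
  vl_assert(is.numeric(baseline_load_mean) && baseline_load_mean > 0,
            "baseline_load_mean must be positive")
  vl_assert(is.numeric(baseline_load_sd) && is.finite(baseline_load_sd),
            "baseline_load_sd must be a finite number")
  vl_assert(is_count(abs(seed)), "seed must be an integer")

  structure(
    list(
      n_patients = as.integer(n_patients),
      exercise_names = exercise_names,
      n_sessions = as.integer(n_sessions),
      population_beta = as.numeric(population_beta),
      sd_exercise = as.numeric(sd_exercise),
      sd_patient = as.numeric(sd_patient),
      sd_patient_exercise = as.numeric(sd_patient_exercise),
      corr_exercise = unname(corr_exercise),
      corr_patient = unname(corr_patient),
      corr_patient_exercise = unname(corr_patient_exercise),
      residual_sd = residual_sd,
      attendance_rate = attendance_rate,
      overshoot_rate = overshoot_rate,
      invalid_rate = invalid_rate,
      baseline_load_mean = baseline_load_mean,
      baseline_load_sd = baseline_load_sd,
      seed = as.integer(seed)
    ),
    class = "vl_generator_config"
  )
}

# Draw zero-mean group effects: n x 3 matrix with given SDs and correlation.
draw_effects <- function(n, sds, corr) {
  z <- matrix(stats::rnorm(n * 3), n, 3)
  if (!all(corr == diag(3))) {
    z <- z %*% chol(corr)
  }
  sweep(z, 2, sds, `*`)
}

# Shared latent structure: group effects, attendance pattern and latent
# trajectories for every patient x exercise x attended analysis session.
simulate_latent <- function(config) {
  set.seed(config$seed)
  J <- length(config$exercise_names)
  P <- config$n_patients
  patients <- sprintf("P%03d", seq_len(P))

  u <- draw_effects(J, config$sd_exercise, config$corr_exercise)
  v <- draw_effects(P, config$sd_patient, config$corr_patient)
  w <- draw_effects(P * J, config$sd_patient_exercise, config$corr_patient_exercise)
  rownames(u) <- config$exercise_names
  rownames(v) <- patients
  # w indexed as (patient-1)*J + exercise
  pe_labels <- character(P * J)
  for (p in seq_len(P)) {
    for (j in seq_len(J)) {
      pe_labels[(p - 1) * J + j] <- paste(patients[p], config$exercise_names[j], sep = ":")
    }
  }
  rownames(w) <- pe_labels
  colnames(u) <- colnames(v) <- colnames(w) <- c("intercept", "linear", "quadratic")

  attended <- matrix(
    stats::runif(P * config$n_sessions) < config$attendance_rate,
    P, config$n_sessions
  )

  rows <- vector("list", P)
  for (p in seq_len(P)) {
    n_att <- sum(attended[p, ])
    if (n_att == 0) next
    t <- seq_len(n_att) - 1
    blocks <- vector("list", J)
    for (j in seq_len(J)) {
      b <- config$population_beta + u[j, ] + v[p, ] + w[(p - 1) * J + j, ]
      mu <- b[1] + b[2] * t + b[3] * t^2
      blocks[[j]] <- tibble::tibble(
        patient_id = patients[p],
        exercise_id = config$exercise_names[j],
        t = t,
        mu = mu
      )
    }
    rows[[p]] <- dplyr::bind_rows(blocks)
  }
  latent <- dplyr::bind_rows(rows)
  latent$z <- latent$mu + stats::rnorm(nrow(latent), 0, config$residual_sd)

  list(
    latent = latent, u = u, v = v, w = w,
    patients = patients, attended = attended
  )
}

#' Simulate standardized volume-load observations
#'
#' Draws a synthetic cohort directly on the standardized (SMD) scale from the
#' three-level quadratic growth model: for patient i, exercise j and attended
#' session t,
#' `z = (b0+u0j+v0i+w0ij) + (b1+u1j+v1i+w1ij) t + (b2+u2j+v2i+w2ij) t^2 + e`,
#' with zero-mean group effects at the configured SDs and Gaussian residual
#' noise. Attendance is an independent Bernoulli draw per patient and
#' scheduled session; `t` counts a patient's attended sessions from 0.
#'
#' @param config a [generator_config()].
#' @return an object of class `vl_sim`: a list with `observations` (a tibble
#'   with columns `patient_id`, `exercise_id`, `t`, `z`), `truth` (the group
#'   effect matrices `u`, `v`, `w`, the population coefficients, and all
#'   generating SDs) and `config`. The truth is returned so parameter-recovery
#'   experiments can compare fitted posteriors against the generating values.
#' @export
generate_standardized <- function(config) {
  vl_assert(inherits(config, "vl_generator_config"),
            "config must be created by generator_config()")
  sim <- simulate_latent(config)
  obs <- sim$latent[, c("patient_id", "exercise_id", "t", "z")]
  structure(
    list(
      observations = obs,
      truth = list(
        beta = config$population_beta,
        u = sim$u, v = sim$v, w = sim$w,
        sd_exercise = config$sd_exercise,
        sd_patient = config$sd_patient,
        sd_patient_exercise = config$sd_patient_exercise,
        residual_sd = config$residual_sd
      ),
      config = config
    ),
    class = "vl_sim"
  )
}

#' Simulate a raw training log
#'
#' Inverts the standardized trajectories of [generate_standardized()] into
#' raw session records (kg loads, sets, repetitions) so that the outcome
#' construction pipeline has realistic input. The target volume-load for a
#' latent value `z` is `M + S * z` with `M = baseline_load_mean * 36` and
#' `S = baseline_load_sd * 36` (3 sets x 12 reps by default); the implied
#' load is rounded to 0.25 kg, the granularity of typical machine weight
#' stacks. Each patient gets two leading familiarization sessions. At the
#' configured rates, sessions are injected with repetition overshoots
#' (13-15 reps per set, load unchanged) or made invalid (two sets, or mean
#' repetitions of eight or fewer).
#'
#' The raw-scale mapping is a modelling stand-in: machine-load distributions
#' of the motivating trials are not published, so the anchors carry no
#' information beyond placing volume-load on a plausible kilogram scale.
#'
#' @param config a [generator_config()] with `baseline_load_sd > 0`.
#' @return an object of class `vl_raw_sim`: a list with `log` (a tibble with
#'   columns `patient_id`, `exercise_id`, `session_index`, `load_kg`,
#'   `n_sets`, `reps` as a semicolon-joined string), `truth` (as in
#'   [generate_standardized()], plus the per-exercise volume-load anchors
#'   `vl_mean`, `vl_sd` and the latent `z` table), and `config`.
#' @export
generate_raw_log <- function(config) {
  vl_assert(inherits(config, "vl_generator_config"),
            "config must be created by generator_config()")
  vl_assert(config$baseline_load_sd > 0,
            "baseline_load_sd must be > 0 to invert onto the raw scale")
  sim <- simulate_latent(config)
  latent <- sim$latent

  vl_mean <- config$baseline_load_mean * 36
  vl_sd <- config$baseline_load_sd * 36

  # analysis sessions: invert z -> load, then inject protocol noise
  vl_target <- vl_mean + vl_sd * latent$z
  load <- pmax(round((vl_target / 36) * 4) / 4, 0.25)

  n <- nrow(latent)
  u_type <- stats::runif(n)
  is_invalid <- u_type < config$invalid_rate
  is_overshoot <- !is_invalid & u_type < config$invalid_rate + config$overshoot_rate

  n_sets <- rep(3L, n)
  reps <- rep("12;12;12", n)

  if (any(is_overshoot)) {
    k <- sum(is_overshoot)
    over <- matrix(sample(13:15, 3 * k, replace = TRUE), k, 3)
    reps[is_overshoot] <- apply(over, 1, paste, collapse = ";")
  }
  if (any(is_invalid)) {
    k <- sum(is_invalid)
    two_sets <- stats::runif(k) < 0.5
    inv_reps <- character(k)
    inv_sets <- integer(k)
    low <- matrix(sample(5:8, 3 * k, replace = TRUE), k, 3)
    for (i in seq_len(k)) {
      if (two_sets[i]) {
        inv_sets[i] <- 2L
        inv_reps[i] <- "12;12"
      } else {
        inv_sets[i] <- 3L
        inv_reps[i] <- paste(low[i, ], collapse = ";")
      }
    }
    n_sets[is_invalid] <- inv_sets
    reps[is_invalid] <- inv_reps
  }

  analysis <- tibble::tibble(
    patient_id = latent$patient_id,
    exercise_id = latent$exercise_id,
    session_index = latent$t + 3L,  # sessions 1-2 are familiarization
    load_kg = load,
    n_sets = n_sets,
    reps = reps
  )

  # familiarization: lighter technique-learning sessions at ~85% of the
  # patient's starting load, always attended
  first_row <- latent$t == 0
  fam_load <- pmax(round((load[first_row] * 0.85) * 4) / 4, 0.25)
  fam_one <- function(idx) {
    tibble::tibble(
      patient_id = latent$patient_id[first_row],
      exercise_id = latent$exercise_id[first_row],
      session_index = idx,
      load_kg = fam_load,
      n_sets = 3L,
      reps = "12;12;12"
    )
  }
  fam <- dplyr::bind_rows(fam_one(1L), fam_one(2L))

  log <- dplyr::arrange(
    dplyr::bind_rows(fam, analysis),
    .data$patient_id, .data$exercise_id, .data$session_index
  )

  structure(
    list(
      log = log,
      truth = list(
        beta = config$population_beta,
        u = sim$u, v = sim$v, w = sim$w,
        sd_exercise = config$sd_exercise,
        sd_patient = config$sd_patient,
        sd_patient_exercise = config$sd_patient_exercise,
        residual_sd = config$residual_sd,
        vl_mean = vl_mean, vl_sd = vl_sd,
        latent = sim$latent[, c("patient_id", "exercise_id", "t", "z")]
      ),
      config = config
    ),
    class = "vl_raw_sim"
  )
}

#' Write a training log as CSV
#'
#' Uses the package's training-log dialect: header
#' `patient_id,exercise_id,session_index,load_kg,n_sets,reps`, with `reps`
#' as semicolon-joined integers.
#'
#' @param log a training-log tibble (e.g. `generate_raw_log(cfg)$log`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  cols <- c("patient_id", "exercise_id", "session_index", "load_kg", "n_sets", "reps")
  vl_assert(all(cols %in% names(log)), "log is missing required columns")
  utils::write.csv(as.data.frame(log[, cols]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
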