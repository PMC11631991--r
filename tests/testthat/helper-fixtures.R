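# Fixtures built in code: a tiny handcrafted training log, degenerate
# posterior draws for plug-in checks, and small seeded cohorts.

# Two patients, one exercise, hand-written sessions. Sessions 1-2 are
# familiarization; analysis sessions carry simple loads.
toy_log <- function() {
  tibble::tibble(
    patient_id = rep(c("A", "B"), each = 6),
    exercise_id = "press",
    session_index = rep(1:6, 2),
    load_kg = c(30, 30, 50, 52.5, 52.5, 55,
                30, 30, 40, 40, 42.5, 42.5),
    n_sets = 3L,
    reps = "12;12;12"
  )
}

# point-mass draws: every draw equals the supplied values
degenerate_draws <- function(beta = c(0.049, 0.093, -0.002),
                             sigma_exercise = c(0.047, 0.043, 0.002),
                             sigma_patient = c(1.007, 0.155, 0.008),
                             sigma_patient_exercise = NULL,
                             n = 200) {
  const <- function(v) {
    if (is.null(v)) return(NULL)
    matrix(rep(v, each = n), nrow = n,
           dimnames = list(NULL, c("intercept", "linear", "quadratic")))
  }
  vl_draws(
    beta = const(beta),
    sigma_exercise = const(sigma_exercise),
    sigma_patient = const(sigma_patient),
    sigma_patient_exercise = const(sigma_patient_exercise),
    sigma_residual = rep(0.25, n)
  )
}

# small cohort used by fitting tests: full attendance, clean protocol
small_cohort <- function(seed = 11, n_patients = 20, n_exercises = 4,
                         n_sessions = 12, ...) {
  generator_config(
    n_patients = n_patients,
    exercise_names = paste0("ex", seq_len(n_exercises)),
    n_sessions = n_sessions,
    attendance_rate = 1, overshoot_rate = 0, invalid_rate = 0,
    seed = seed, ...
  )
}

fast_config <- function(seed = 5, ...) {
  model_config(chains = 2, iterations = 800, adapt = 150, seed = seed,
               target_rhat = 1.2, ...)
}
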