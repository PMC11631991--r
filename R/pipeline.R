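# End-to-end orchestration: configuration, log ingestion, staged execution
# and CSV/JSON reporting.

#' Read a training log CSV
#'
#' Parses the package's training-log dialect (header
#' `patient_id,exercise_id,session_index,load_kg,n_sets,reps`, repetitions
#' semicolon-joined) with validation: missing columns are named, and
#' malformed rows (non-numeric load, non-positive load, repetition count
#' disagreeing with `n_sets`) are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return a training-log tibble.
#' @export
read_training_log <- function(path) {
  vl_assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("patient_id", "exercise_id", "session_index", "load_kg",
                "n_sets", "reps")
  missing <- setdiff(required, names(raw))
  vl_assert(length(missing) == 0, "missing column(s): %s",
            paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      patient_id = character(0), exercise_id = character(0),
      session_index = integer(0), load_kg = numeric(0),
      n_sets = integer(0), reps = character(0)
    ))
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  load_kg <- suppressWarnings(as.numeric(raw$load_kg))
  n_sets <- suppressWarnings(as.integer(raw$n_sets))
  session_index <- suppressWarnings(as.integer(raw$session_index))
  reps_len <- vapply(strsplit(raw$reps, ";", fixed = TRUE), length, integer(1))
  reps_num <- vapply(parse_reps(raw$reps),
                     function(r) all(is.finite(r)) && all(r >= 0), logical(1))
  bad <- is.na(load_kg) | load_kg <= 0 | is.na(n_sets) | is.na(session_index) |
    !reps_num | reps_len != n_sets
  if (any(bad)) {
    stop(sprintf("malformed row(s) at line(s): %s",
                 paste(line[bad], collapse = ", ")), call. = FALSE)
  }
  key <- paste(raw$patient_id, raw$exercise_id, session_index)
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("duplicate patient/exercise/session at line(s): %s",
                 paste(line[dup], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    patient_id = raw$patient_id, exercise_id = raw$exercise_id,
    session_index = session_index, load_kg = load_kg,
    n_sets = n_sets, reps = raw$reps
  )
}

#' Assemble a pipeline run configuration
#'
#' @param stages character vector of stages to execute, a subset of
#'   `c("simulate", "construct", "fit", "derive", "compare", "plan")`.
#'   Stages consume the outputs of earlier ones; `construct` reads
#'   `input_log` when `simulate` is not selected.
#' @param generator a [generator_config()] (used by `simulate`).
#' @param model a [model_config()] (used by `fit` and `compare`).
#' @param input_log optional path to a training-log CSV.
#' @param n_mc Monte-Carlo pairs for plateau propagation.
#' @param responder_threshold slope threshold for responder labels.
#' @param attendance_fractions fractions for the sensitivity refits.
#' @param progression parameters for the `plan` stage: list with `initial`,
#'   `pct`, `decay`, `n_progressions`.
#' @param seed global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @return an object of class `vl_run_config`.
#' @export
run_config <- function(stages = c("simulate", "construct", "fit", "derive",
                                  "compare", "plan"),
                       generator = generator_config(),
                       model = model_config(),
                       input_log = NULL,
                       n_mc = 10000,
                       responder_threshold = 0,
                       attendance_fractions = c(0.5, 0.75),
                       progression = list(initial = 50, pct = 0.05,
                                          decay = 0.04, n_progressions = 5),
                       seed = 1L) {
  known <- c("simulate", "construct", "fit", "derive", "compare", "plan")
  vl_assert(all(stages %in% known), "unknown stage(s): %s",
            paste(setdiff(stages, known), collapse = ", "))
  vl_assert(inherits(generator, "vl_generator_config"),
            "generator must come from generator_config()")
  vl_assert(inherits(model, "vl_model_config"),
            "model must come from model_config()")
  structure(
    list(stages = stages, generator = generator, model = model,
         input_log = input_log, n_mc = n_mc,
         responder_threshold = responder_threshold,
         attendance_fractions = attendance_fractions,
         progression = progression, seed = as.integer(seed)),
    class = "vl_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Reads a structured-text configuration with optional blocks `generator`,
#' `model` (with optional `priors`), and scalar settings mirroring the
#' arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return an object of class `vl_run_config`.
#' @export
read_run_config <- function(path) {
  vl_assert(file.exists(path), "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  gen <- do.call(generator_config, y$generator %||% list())
  model_args <- y$model %||% list()
  if (!is.null(model_args$priors)) {
    model_args$priors <- do.call(default_priors, model_args$priors)
  }
  mod <- do.call(model_config, model_args)
  run_config(
    stages = y$stages %||% c("simulate", "construct", "fit", "derive",
                             "compare", "plan"),
    generator = gen, model = mod,
    input_log = y$input_log,
    n_mc = y$n_mc %||% 10000,
    responder_threshold = y$responder_threshold %||% 0,
    attendance_fractions = y$attendance_fractions %||% c(0.5, 0.75),
    progression = y$progression %||% list(initial = 50, pct = 0.05,
                                          decay = 0.04, n_progressions = 5),
    seed = y$seed %||% 1L
  )
}

write_table <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order — simulate a cohort, construct the
#' standardized outcome, fit the growth model, derive posterior summaries
#' (population/exercise/plateau tables, responder and within-individual
#' tables), compare linear vs quadratic per-exercise fits and tabulate
#' load-change frequencies, and emit a progression plan — writing every
#' table as CSV under `out_dir` together with a machine-readable run
#' manifest (stages, seed, configuration fingerprint, package version,
#' removal counts). A stage failure aborts the run with the failing stage
#' named; tables already written are retained alongside a `FAILED` marker.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param out_dir output directory, created if needed.
#' @param seed optional override of the config's global seed.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  vl_assert(inherits(config, "vl_run_config"), "config must come from run_config()")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  manifest <- list(
    stages = config$stages,
    seed = config$seed,
    config_fingerprint = fnv1a_hash(paste(
      jsonlite::toJSON(unclass(config$generator), auto_unbox = TRUE, digits = NA),
      jsonlite::toJSON(unclass(config$model)[setdiff(names(config$model), "priors")],
                       auto_unbox = TRUE, digits = NA)
    )),
    package_version = as.character(utils::packageVersion("vltraj")),
    tables = character(0)
  )
  current_stage <- NULL

  emit <- function(df, name) {
    write_table(df, out_dir, name)
    manifest$tables <<- c(manifest$tables, paste0(name, ".csv"))
  }

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    current_stage <<- name
    fun()
  }

  tryCatch({
    run_stage("simulate", function() {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, "simulate")
      raw <- generate_raw_log(gen)
      results$raw <<- raw
      write_training_log(raw$log, file.path(out_dir, "training_log.csv"))
      manifest$tables <<- c(manifest$tables, "training_log.csv")
      # generating truth (group effects) and the exact config used
      tr <- raw$truth
      effect_rows <- function(m, level) tibble::tibble(
        level = level, group = rownames(m),
        intercept = m[, 1], linear = m[, 2], quadratic = m[, 3]
      )
      emit(dplyr::bind_rows(effect_rows(tr$u, "exercise"),
                            effect_rows(tr$v, "patient"),
                            effect_rows(tr$w, "patient_exercise")),
           "truth_effects")
      gen_plain <- unclass(gen)
      gen_plain[c("corr_exercise", "corr_patient", "corr_patient_exercise")] <-
        lapply(gen_plain[c("corr_exercise", "corr_patient",
                           "corr_patient_exercise")], as.vector)
      yaml::write_yaml(gen_plain, file.path(out_dir, "generator_config.yaml"))
      manifest$tables <<- c(manifest$tables, "generator_config.yaml")
    })

    run_stage("construct", function() {
      log <- if (!is.null(results$raw)) {
        results$raw$log
      } else {
        vl_assert(!is.null(config$input_log),
                  "construct stage needs input_log when simulate is not run")
        read_training_log(config$input_log)
      }
      outcome <- construct_outcome(log)
      results$outcome <<- outcome
      emit(outcome$observations, "observations")
      emit(outcome$baseline, "baseline_stats")
      manifest$removed <<- as.list(outcome$removed)
    })

    run_stage("fit", function() {
      obs <- results$outcome$observations %||% results$sim$observations
      vl_assert(!is.null(obs), "fit stage needs observations from construct")
      mcfg <- config$model
      mcfg$seed <- stage_seed(config$seed, "fit")
      draws <- fit_growth_model(build_model(obs, mcfg), mcfg)
      results$draws <<- draws
      emit(summarize_posterior(draws), "population_summary")
      emit(draws$diagnostics, "diagnostics")
      write_draws(draws, file.path(out_dir, "draws.csv"))
      manifest$tables <<- c(manifest$tables, "draws.csv")
    })

    run_stage("derive", function() {
      draws <- results$draws
      vl_assert(!is.null(draws), "derive stage needs a fitted model")
      dseed <- stage_seed(config$seed, "derive")

      ex_tab <- exercise_trajectories(draws)
      emit(ex_tab, "exercise_trajectories")

      hi_rows <- lapply(c("exercise", "full"), function(lv) {
        lapply(c("intercept", "linear", "quadratic"), function(p) {
          h <- heterogeneity_interval(draws, lv, p)
          tibble::tibble(level = lv, parameter = p,
                         lower_mean = h$lower_mean, upper_mean = h$upper_mean,
                         lower_ui_lo = h$lower_ui[1], lower_ui_hi = h$lower_ui[2],
                         upper_ui_lo = h$upper_ui[1], upper_ui_hi = h$upper_ui[2])
        })
      })
      emit(dplyr::bind_rows(unlist(hi_rows, recursive = FALSE)),
           "heterogeneity_intervals")

      scopes <- c("population", dimnames(draws$u)[[2]])
      plateau <- dplyr::bind_rows(lapply(scopes, function(sc) {
        p <- plateau_distribution(draws, sc, n_mc = config$n_mc, seed = dseed)
        tibble::tibble(scope = sc, mean = p$mean, median = p$median, sd = p$sd,
                       lower_ui = p$lower_ui, upper_ui = p$upper_ui,
                       prop_nonconcave = p$prop_nonconcave)
      }))
      emit(plateau, "plateau")

      cv <- coefficient_of_variation(draws, "linear")
      vr_lin <- variance_ratio(draws, "linear")
      vr_quad <- variance_ratio(draws, "quadratic")
      emit(tibble::tibble(
        quantity = c("cv_exercise_linear_pct", "variance_ratio_linear",
                     "variance_ratio_quadratic"),
        estimate = c(cv$median, vr_lin$mean, vr_quad$mean),
        lower = c(cv$lower, vr_lin$lower, vr_quad$lower),
        upper = c(cv$upper, vr_lin$upper, vr_quad$upper)
      ), "variability_summaries")

      if (!is.null(draws$w)) {
        resp <- classify_responders(draws, config$responder_threshold)
        emit(resp$by_exercise, "responders_by_exercise")
        emit(resp$by_patient, "responders_by_patient")
        wiv <- within_individual_variability(draws)
        emit(wiv$per_patient, "within_individual")
        manifest$within_individual <<- list(
          median = wiv$median, range = wiv$range,
          correlation = wiv$correlation
        )
      }
    })

    run_stage("compare", function() {
      obs <- results$outcome$observations
      vl_assert(!is.null(obs), "compare stage needs observations")
      mcfg <- config$model
      mcfg$seed <- stage_seed(config$seed, "compare")
      loo_tabs <- lapply(sort(unique(obs$exercise_id)), function(e) {
        compare_loo(fit_exercise_pair(obs, e, mcfg))
      })
      emit(dplyr::bind_rows(loo_tabs), "loo_comparison")
      if (!is.null(results$raw)) {
        emit(half_frequencies(results$raw$log), "half_frequencies")
      }
      sens <- sensitivity_refit(obs, mcfg,
                                fractions = config$attendance_fractions)
      emit(sens, "sensitivity_attendance")
    })

    run_stage("plan", function() {
      pr <- config$progression
      plan_c <- progression_plan(pr$initial, pr$pct, pr$n_progressions, "classic")
      plan_d <- progression_plan(pr$initial, pr$pct, pr$n_progressions, "corrected",
                                 decay = pr$decay)
      emit(tibble::tibble(
        step = plan_c$step,
        classic_kg = plan_c$load_kg,
        corrected_kg = plan_d$load_kg
      ), "progression_plan")
    })
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", current_stage %||% "?",
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s",
                 current_stage %||% "?", conditionMessage(e)), call. = FALSE)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}
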