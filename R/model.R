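#' Prior sets for the growth model
#'
#' Three prior modes are provided. `weakly_informative` (the default) places
#' zero-centred unit-scale normals on the population coefficients and
#' half-normal(1) priors on every SD; on the standardized outcome scale these
#' are broad but proper. `diffuse` widens every scale to 10 and is used for
#' prior-sensitivity reruns. `user_supplied` takes explicit locations and
#' scales, the hook for priors elicited from external evidence such as a
#' meta-analysis of training studies.
#'
#' @param mode one of `"weakly_informative"`, `"diffuse"`, `"user_supplied"`.
#' @param beta_location,beta_scale length-3 numerics for the population
#'   intercept/linear/quadratic priors (required for `user_supplied`).
#' @param sd_scale named numeric with entries `exercise`, `patient`,
#'   `patient_exercise`, `residual`: half-normal scales for the group and
#'   residual SDs (required for `user_supplied`).
#' @return an object of class `vl_priors`.
#' @export
default_priors <- function(mode = c("weakly_informative", "diffuse", "user_supplied"),
                           beta_location = NULL, beta_scale = NULL,
                           sd_scale = NULL) {
  mode <- match.arg(mode)
  sd_names <- c("exercise", "patient", "patient_exercise", "residual")
  if (mode == "weakly_informative") {
    beta_location <- c(0, 0, 0)
    beta_scale <- c(1, 1, 1)
    sd_scale <- stats::setNames(rep(1, 4), sd_names)
  } else if (mode == "diffuse") {
    beta_location <- c(0, 0, 0)
    beta_scale <- c(10, 10, 10)
    sd_scale <- stats::setNames(rep(10, 4), sd_names)
  } else {
    for (nm in c("beta_location", "beta_scale", "sd_scale")) {
      vl_assert(!is.null(get(nm)), "user_supplied priors require field '%s'", nm)
    }
    vl_assert(length(beta_location) == 3 && all(is.finite(beta_location)),
              "beta_location must be three finite numbers")
    vl_assert(length(beta_scale) == 3 && all(beta_scale > 0),
              "beta_scale must be three positive numbers")
    vl_assert(all(sd_names %in% names(sd_scale)),
              "sd_scale must name entries: %s", paste(sd_names, collapse = ", "))
    vl_assert(all(sd_scale[sd_names] > 0), "sd_scale entries must be positive")
    sd_scale <- sd_scale[sd_names]
  }
  structure(
    list(mode = mode,
         beta_location = as.numeric(beta_location),
         beta_scale = as.numeric(beta_scale),
         sd_scale = stats::setNames(as.numeric(sd_scale), sd_names)),
    class = "vl_priors"
  )
}

#' Configuration for fitting the growth model
#'
#' @param grouping `"three_level"` (default: exercise, patient and
#'   patient-by-exercise effects) or `"two_level"` (exercise and patient
#'   only, mirroring a report restricted to those two variance components).
#'   Within-individual analytics require `"three_level"`.
#' @param priors a [default_priors()] object.
#' @param chains number of MCMC chains (>= 2).
#' @param iterations total iterations per chain (>= 200); the first half is
#'   discarded as warmup.
#' @param adapt sampler adaptation iterations before warmup.
#' @param seed integer seed; chain RNGs are derived from it.
#' @param target_rhat convergence threshold on split-chain R-hat for the
#'   reported parameters.
#' @param on_nonconvergence `"warn"` (default) or `"error"` when any reported
#'   parameter exceeds `target_rhat`.
#' @return an object of class `vl_model_config`.
#' @export
model_config <- function(grouping = c("three_level", "two_level"),
                         priors = default_priors(),
                         chains = 4, iterations = 2000, adapt = 300,
                         seed = 1L, target_rhat = 1.01,
                         on_nonconvergence = c("warn", "error")) {
  grouping <- match.arg(grouping)
  on_nonconvergence <- match.arg(on_nonconvergence)
  vl_assert(inherits(priors, "vl_priors"), "priors must come from default_priors()")
  vl_assert(is_count(chains, 2L), "chains must be an integer >= 2")
  vl_assert(is_count(iterations, 200L), "iterations must be an integer >= 200")
  vl_assert(is_count(adapt, 1L), "adapt must be a positive integer")
  structure(
    list(grouping = grouping, priors = priors,
         chains = as.integer(chains), iterations = as.integer(iterations),
         adapt = as.integer(adapt), seed = as.integer(seed),
         target_rhat = target_rhat, on_nonconvergence = on_nonconvergence),
    class = "vl_model_config"
  )
}

# assemble JAGS code for a varying-coefficient Gaussian model with any
# subset of the levels {exercise, patient, patient_exercise} and K design
# columns (K = 2 linear, K = 3 quadratic)
jags_code <- function(levels) {
  terms <- c("inprod(X[n, 1:K], beta)")
  blocks <- character(0)
  if ("exercise" %in% levels) {
    terms <- c(terms, "inprod(X[n, 1:K], u[ex[n], 1:K])")
    blocks <- c(blocks, "
    for (j in 1:J) { u[j, k] ~ dnorm(0, pow(sig_u[k], -2)) }
    sig_u[k] ~ dnorm(0, pow(scale_u, -2)) T(0,)")
  }
  if ("patient" %in% levels) {
    terms <- c(terms, "inprod(X[n, 1:K], v[pat[n], 1:K])")
    blocks <- c(blocks, "
    for (p in 1:P) { v[p, k] ~ dnorm(0, pow(sig_v[k], -2)) }
    sig_v[k] ~ dnorm(0, pow(scale_v, -2)) T(0,)")
  }
  if ("patient_exercise" %in% levels) {
    terms <- c(terms, "inprod(X[n, 1:K], w[pe[n], 1:K])")
    blocks <- c(blocks, "
    for (q in 1:Q) { w[q, k] ~ dnorm(0, pow(sig_w[k], -2)) }
    sig_w[k] ~ dnorm(0, pow(scale_w, -2)) T(0,)")
  }
  paste0("model {
  for (n in 1:N) {
    mu[n] <- ", paste(terms, collapse = " +\n             "), "
    z[n] ~ dnorm(mu[n], tau_res)
  }
  for (k in 1:K) {
    beta[k] ~ dnorm(beta_loc[k], pow(beta_scale[k], -2))",
  paste(blocks, collapse = ""), "
  }
  tau_res <- pow(sig_res, -2)
  sig_res ~ dnorm(0, pow(scale_res, -2)) T(0,)
}
")
}

# shared model assembly; `degree` = 2 (linear) or 3 (quadratic columns)
build_model_impl <- function(observations, config, levels, degree = 3) {
  obs <- observations
  vl_assert(all(c("patient_id", "exercise_id", "t", "z") %in% names(obs)),
            "observations need columns patient_id, exercise_id, t, z")
  vl_assert(nrow(obs) > 0, "no observations")
  vl_assert(all(is.finite(obs$z)), "non-finite outcome values")
  exercises <- sort(unique(obs$exercise_id))
  patients <- sort(unique(obs$patient_id))
  vl_assert(length(unique(obs$t)) >= 3, "need at least 3 distinct session times")
  if ("patient" %in% levels) {
    vl_assert(length(patients) >= 2, "need at least 2 patients")
  }
  if ("patient_exercise" %in% levels && length(exercises) < 2) {
    stop("single-exercise data: use grouping = 'two_level' (no patient-by-exercise term)",
         call. = FALSE)
  }
  if ("exercise" %in% levels && length(exercises) < 2) {
    # a lone exercise is indistinguishable from the population: model it
    # through the population coefficients alone
    levels <- setdiff(levels, "exercise")
  }

  ex <- match(obs$exercise_id, exercises)
  pat <- match(obs$patient_id, patients)
  K <- degree
  X <- cbind(1, obs$t, obs$t^2)[, seq_len(K), drop = FALSE]

  pr <- config$priors
  data <- list(
    N = nrow(obs), K = K, X = X, z = as.numeric(obs$z),
    beta_loc = pr$beta_location[seq_len(K)],
    beta_scale = pr$beta_scale[seq_len(K)],
    scale_res = unname(pr$sd_scale["residual"])
  )
  if ("exercise" %in% levels) {
    data$ex <- ex; data$J <- length(exercises)
    data$scale_u <- unname(pr$sd_scale["exercise"])
  }
  if ("patient" %in% levels) {
    data$pat <- pat; data$P <- length(patients)
    data$scale_v <- unname(pr$sd_scale["patient"])
  }
  if ("patient_exercise" %in% levels) {
    pe_key <- paste(obs$patient_id, obs$exercise_id, sep = ":")
    pe_levels <- sort(unique(pe_key))
    data$pe <- match(pe_key, pe_levels)
    data$Q <- length(pe_levels)
    data$scale_w <- unname(pr$sd_scale["patient_exercise"])
  } else {
    pe_levels <- NULL
  }

  structure(
    list(
      code = jags_code(levels),
      data = data,
      levels = levels,
      degree = K,
      labels = list(exercises = exercises, patients = patients,
                    patient_exercise = pe_levels),
      config = config
    ),
    class = "vl_model"
  )
}

#' Build the hierarchical growth model
#'
#' Specifies the varying-coefficient quadratic regression of standardized
#' volume-load `z` on session time `t`:
#' `z = (b0+u0+v0+w0) + (b1+u1+v1+w1) t + (b2+u2+v2+w2) t^2 + e`, with
#' Gaussian level-1 error and zero-mean group effects for exercises (`u`),
#' patients (`v`) and, under `three_level` grouping, patient-by-exercise
#' combinations (`w`). Effects are modelled independently across the three
#' coefficients within a level, with half-normal priors on each SD.
#'
#' @param observations a standardized-observation tibble (`patient_id`,
#'   `exercise_id`, `t`, `z`).
#' @param config a [model_config()].
#' @return an object of class `vl_model` holding the sampler code, data
#'   block and group labels; pass to [fit_growth_model()].
#' @export
build_model <- function(observations, config = model_config()) {
  vl_assert(inherits(config, "vl_model_config"),
            "config must come from model_config()")
  levels <- switch(config$grouping,
    three_level = c("exercise", "patient", "patient_exercise"),
    two_level = c("exercise", "patient")
  )
  build_model_impl(observations, config, levels, degree = 3)
}

coef_names <- c("intercept", "linear", "quadratic")

# split a coda::mcmc.list into a draws matrix (chains stacked)
stack_chains <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

# extract an indexed parameter block "name[i,k]" into a ndraw x n x K array
extract_block <- function(draws_mat, name, n, K, labels) {
  arr <- array(NA_real_, c(nrow(draws_mat), n, K),
               dimnames = list(NULL, labels, coef_names[seq_len(K)]))
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      arr[, i, k] <- draws_mat[, sprintf("%s[%d,%d]", name, i, k)]
    }
  }
  arr
}

#' Fit the growth model by MCMC
#'
#' Samples the joint posterior with Gibbs updates (JAGS, with its block-GLM
#' sampler enabled). The first half of each chain is discarded as warmup.
#' Split-chain R-hat and effective sample sizes are computed for all reported
#' parameters (population coefficients, group SDs, residual SD); if any
#' R-hat exceeds the configured threshold the fit warns or errors per
#' `config$on_nonconvergence`, carrying the diagnostics table.
#'
#' @param model a [build_model()] specification.
#' @param config optional [model_config()] overriding the one stored in the
#'   model.
#' @return an object of class `vl_draws` with elements `beta` (draws x
#'   coefficient matrix), `sigma` (list of SD draw matrices per level plus
#'   the residual vector), `u`, `v`, `w` (group-effect draw arrays),
#'   `labels`, `diagnostics` and the model `data` needed for pointwise
#'   log-likelihood evaluation.
#' @export
fit_growth_model <- function(model, config = NULL) {
  vl_assert(inherits(model, "vl_model"), "model must come from build_model()")
  config <- config %||% model$config
  levels <- model$levels
  K <- model$degree

  if (!("glm" %in% rjags::list.modules())) {
    rjags::load.module("glm", quiet = TRUE)
  }

  inits <- lapply(seq_len(config$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(config$seed) * 97 + ch) %% (2^31 - 1))
  })

  monitors <- c("beta", "sig_res")
  if ("exercise" %in% levels) monitors <- c(monitors, "sig_u", "u")
  if ("patient" %in% levels) monitors <- c(monitors, "sig_v", "v")
  if ("patient_exercise" %in% levels) monitors <- c(monitors, "sig_w", "w")

  warmup <- config$iterations %/% 2
  keep <- config$iterations - warmup

  jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                          n.chains = config$chains, n.adapt = config$adapt,
                          inits = inits, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitors, n.iter = keep,
                                 progress.bar = "none")

  mat <- stack_chains(samples)
  beta <- mat[, sprintf("beta[%d]", seq_len(K)), drop = FALSE]
  colnames(beta) <- coef_names[seq_len(K)]

  sigma <- list(residual = as.numeric(mat[, "sig_res"]))
  u <- v <- w <- NULL
  if ("exercise" %in% levels) {
    sigma$exercise <- mat[, sprintf("sig_u[%d]", seq_len(K)), drop = FALSE]
    colnames(sigma$exercise) <- coef_names[seq_len(K)]
    u <- extract_block(mat, "u", model$data$J, K, model$labels$exercises)
  }
  if ("patient" %in% levels) {
    sigma$patient <- mat[, sprintf("sig_v[%d]", seq_len(K)), drop = FALSE]
    colnames(sigma$patient) <- coef_names[seq_len(K)]
    v <- extract_block(mat, "v", model$data$P, K, model$labels$patients)
  }
  if ("patient_exercise" %in% levels) {
    sigma$patient_exercise <- mat[, sprintf("sig_w[%d]", seq_len(K)), drop = FALSE]
    colnames(sigma$patient_exercise) <- coef_names[seq_len(K)]
    w <- extract_block(mat, "w", model$data$Q, K, model$labels$patient_exercise)
  }

  reported <- c(sprintf("beta[%d]", seq_len(K)), "sig_res",
                if ("exercise" %in% levels) sprintf("sig_u[%d]", seq_len(K)),
                if ("patient" %in% levels) sprintf("sig_v[%d]", seq_len(K)),
                if ("patient_exercise" %in% levels) sprintf("sig_w[%d]", seq_len(K)))
  reported_samples <- samples[, reported, drop = FALSE]
  rhat <- tryCatch(
    coda::gelman.diag(reported_samples, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, length(reported)), reported)
  )
  ess <- coda::effectiveSize(reported_samples)
  diagnostics <- tibble::tibble(
    parameter = reported,
    rhat = as.numeric(rhat[reported]),
    ess = as.numeric(ess[reported])
  )

  out <- vl_draws(
    beta = beta,
    sigma_exercise = sigma$exercise,
    sigma_patient = sigma$patient,
    sigma_patient_exercise = sigma$patient_exercise,
    sigma_residual = sigma$residual,
    u = u, v = v, w = w,
    diagnostics = diagnostics,
    grouping = if (setequal(levels, c("exercise", "patient", "patient_exercise")))
      "three_level" else if (setequal(levels, c("exercise", "patient")))
      "two_level" else "custom",
    seed = config$seed
  )
  out$data <- model$data
  out$labels <- model$labels

  bad <- diagnostics$rhat > config$target_rhat
  if (any(bad, na.rm = TRUE)) {
    msg <- sprintf(
      "convergence: %d parameter(s) with R-hat > %.3f (worst: %s = %.3f)",
      sum(bad, na.rm = TRUE), config$target_rhat,
      diagnostics$parameter[which.max(diagnostics$rhat)],
      max(diagnostics$rhat, na.rm = TRUE)
    )
    if (config$on_nonconvergence == "error") {
      cond <- structure(
        class = c("vl_convergence_error", "error", "condition"),
        list(message = msg, call = sys.call(-1), diagnostics = diagnostics)
      )
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  out
}

#' Construct a posterior-draws object
#'
#' Low-level constructor for the container [fit_growth_model()] returns.
#' Exposed so derived-quantity functions can be exercised on analytically
#' known draws (e.g. degenerate point-mass draws in plug-in checks).
#'
#' @param beta draws x coefficient matrix of population coefficients
#'   (columns `intercept`, `linear`, `quadratic`).
#' @param sigma_exercise,sigma_patient,sigma_patient_exercise draws x
#'   coefficient matrices of group-level SDs, or `NULL` when the level is
#'   absent.
#' @param sigma_residual numeric vector of residual SD draws, or `NULL`.
#' @param u,v,w group-effect arrays (draws x group x coefficient), or `NULL`.
#' @param diagnostics optional diagnostics tibble.
#' @param grouping `"three_level"`, `"two_level"` or `"custom"`.
#' @param seed the seed used to produce the draws, if any.
#' @return an object of class `vl_draws`.
#' @export
vl_draws <- function(beta, sigma_exercise = NULL, sigma_patient = NULL,
                     sigma_patient_exercise = NULL, sigma_residual = NULL,
                     u = NULL, v = NULL, w = NULL, diagnostics = NULL,
                     grouping = "custom", seed = NULL) {
  beta <- as.matrix(beta)
  vl_assert(ncol(beta) >= 2, "beta needs at least intercept and linear columns")
  if (is.null(colnames(beta))) colnames(beta) <- coef_names[seq_len(ncol(beta))]
  S <- nrow(beta)
  sigma <- list(
    exercise = sigma_exercise, patient = sigma_patient,
    patient_exercise = sigma_patient_exercise
  )
  for (nm in names(sigma)) {
    if (!is.null(sigma[[nm]])) {
      sigma[[nm]] <- as.matrix(sigma[[nm]])
      vl_assert(nrow(sigma[[nm]]) == S, "sigma_%s draw count mismatch", nm)
      vl_assert(all(sigma[[nm]] >= 0), "sigma_%s has negative draws", nm)
      if (is.null(colnames(sigma[[nm]])))
        colnames(sigma[[nm]]) <- coef_names[seq_len(ncol(sigma[[nm]]))]
    }
  }
  if (!is.null(sigma_residual)) {
    vl_assert(length(sigma_residual) == S, "sigma_residual draw count mismatch")
    vl_assert(all(sigma_residual >= 0), "sigma_residual has negative draws")
  }
  sigma$residual <- sigma_residual
  structure(
    list(beta = beta, sigma = sigma, u = u, v = v, w = w,
         diagnostics = diagnostics, grouping = grouping, seed = seed,
         n_draws = S),
    class = "vl_draws"
  )
}

#' @export
print.vl_draws <- function(x, ...) {
  cat(sprintf("<vl_draws> %d draws, grouping: %s\n", x$n_draws, x$grouping))
  print(summarize_posterior(x), n = Inf)
  invisible(x)
}

#' Summarize posterior draws
#'
#' Posterior mean, SD and central 95% uncertainty interval (2.5% and 97.5%
#' quantiles) for every reported parameter, laid out by level: population
#' coefficients first, then the between-exercise, between-patient and (when
#' present) patient-by-exercise SDs, and the residual SD.
#'
#' @param draws a [vl_draws()] object with at least 100 draws.
#' @return a tibble with columns `level`, `parameter`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
summarize_posterior <- function(draws) {
  vl_assert(inherits(draws, "vl_draws"), "draws must be a vl_draws object")
  vl_assert(draws$n_draws >= 100, "need at least 100 draws to summarize")
  row <- function(level, parameter, x) {
    q <- ci95(x)
    tibble::tibble(level = level, parameter = parameter,
                   mean = mean(x), sd = stats::sd(x),
                   lower = q[1], upper = q[2])
  }
  out <- list()
  for (k in colnames(draws$beta)) {
    out[[length(out) + 1]] <- row("population", k, draws$beta[, k])
  }
  for (lv in c("exercise", "patient", "patient_exercise")) {
    s <- draws$sigma[[lv]]
    if (is.null(s)) next
    for (k in colnames(s)) {
      out[[length(out) + 1]] <- row(paste0("sd_", lv), k, s[, k])
    }
  }
  if (!is.null(draws$sigma$residual)) {
    out[[length(out) + 1]] <- row("sd_residual", "residual", draws$sigma$residual)
  }
  dplyr::bind_rows(out)
}

#' Persist posterior draws as a columnar table
#'
#' Writes one CSV column per scalar parameter (population coefficients,
#' SDs, and every group effect) plus a JSON sidecar with metadata: seed,
#' grouping, draw count and a configuration fingerprint.
#'
#' @param draws a [vl_draws()] object.
#' @param path CSV output path; metadata goes to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  cols <- list()
  for (k in colnames(draws$beta)) cols[[paste0("beta_", k)]] <- draws$beta[, k]
  for (lv in c("exercise", "patient", "patient_exercise")) {
    s <- draws$sigma[[lv]]
    if (is.null(s)) next
    for (k in colnames(s)) cols[[paste0("sigma_", lv, "_", k)]] <- s[, k]
  }
  if (!is.null(draws$sigma$residual)) cols[["sigma_residual"]] <- draws$sigma$residual
  for (blk in c("u", "v", "w")) {
    arr <- draws[[blk]]
    if (is.null(arr)) next
    dn <- dimnames(arr)
    for (i in seq_len(dim(arr)[2])) {
      for (k in seq_len(dim(arr)[3])) {
        cols[[sprintf("%s.%s.%s", blk, dn[[2]][i], dn[[3]][k])]] <- arr[, i, k]
      }
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(seed = draws$seed, grouping = draws$grouping,
               n_draws = draws$n_draws,
               fingerprint = fnv1a_hash(paste(names(cols), collapse = ",")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

# pointwise log-likelihood matrix (draws x observations) for a fitted model;
# requires the model data stored by fit_growth_model()
loglik_matrix <- function(draws) {
  vl_assert(!is.null(draws$data), "draws carry no model data")
  d <- draws$data
  S <- draws$n_draws
  K <- d$K
  X <- d$X
  mu <- draws$beta[, seq_len(K), drop = FALSE] %*% t(X)  # S x N population part
  add_level <- function(mu, arr, idx) {
    if (is.null(arr)) return(mu)
    for (k in seq_len(K)) {
      mu <- mu + arr[, idx, k] * matrix(X[, k], nrow = S, ncol = length(idx), byrow = TRUE)
    }
    mu
  }
  mu <- add_level(mu, draws$u, d$ex)
  mu <- add_level(mu, draws$v, d$pat)
  mu <- add_level(mu, draws$w, d$pe)
  z <- matrix(d$z, nrow = S, ncol = d$N, byrow = TRUE)
  sd <- draws$sigma$residual
  stats::dnorm(z, mu, sd, log = TRUE)
}
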