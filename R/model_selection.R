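# Leave-one-out cross-validation via Pareto-smoothed importance sampling,
# and the surrounding model-comparison machinery.

# Generalized-Pareto fit to exceedances x > 0 (profile-likelihood posterior
# mean over a grid, with a weak prior pulling the shape toward 0.5).
# Returns the tail-shape k (k > 0.7 signals unreliable importance weights)
# and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  vl_assert(n >= 5, "too few tail samples for a generalized-Pareto fit")
  m <- 30 + floor(sqrt(n))
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of <- function(th) -mean(log1p(-th * x))  # profile estimate, sign flipped vs tail shape
  ks <- vapply(theta, k_of, numeric(1))
  l_theta <- n * (log(theta / ks) + ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l_theta - l_theta[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k_prof <- k_of(theta_hat)
  sigma_hat <- k_prof / theta_hat
  xi_hat <- -k_prof
  # regularize the shape toward 0.5 as if by 10 prior pseudo-observations
  xi_hat <- (n * xi_hat + 10 * 0.5) / (n + 10)
  list(k = xi_hat, sigma = sigma_hat)
}

# quantile function of the fitted GPD (exceedance scale), shape k, scale sigma
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling LOO
#'
#' Estimates the expected log pointwise predictive density (elpd) under
#' leave-one-out cross-validation from a pointwise log-likelihood matrix.
#' For each observation, the raw importance ratios `1/p(y_i | theta_s)` have
#' their upper tail (the largest `min(0.2 S, 3 sqrt(S))` ratios) replaced by
#' expected order statistics of a generalized-Pareto distribution fitted to
#' that tail, then truncated at the raw maximum. The fitted tail shape `k`
#' is reported per observation; values above 0.7 flag unreliable estimates.
#'
#' @param loglik draws x observations matrix of pointwise log-likelihoods.
#' @return a list of class `vl_loo` with `elpd`, `se`, `pointwise` (per
#'   observation elpd), `pareto_k`, and `n_bad_k` (count with k > 0.7).
#' @export
psis_loo <- function(loglik) {
  vl_assert(is.matrix(loglik) && nrow(loglik) >= 100,
            "loglik must be a draws x observations matrix with >= 100 draws")
  S <- nrow(loglik)
  N <- ncol(loglik)
  n_tail <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  pointwise <- numeric(N)
  pareto_k <- numeric(N)
  for (i in seq_len(N)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    ord <- order(lw)
    tail_ids <- ord[(S - n_tail + 1):S]
    cutoff <- lw[ord[S - n_tail]]
    exceed <- exp(lw[tail_ids]) - exp(cutoff)
    if (stats::sd(exceed) < 1e-12) {
      pareto_k[i] <- -Inf  # degenerate tail: nothing to smooth
    } else {
      fit <- gpd_fit(exceed)
      pareto_k[i] <- fit$k
      p <- (seq_len(n_tail) - 0.5) / n_tail
      smoothed <- log(exp(cutoff) + gpd_quantile(p, fit$k, fit$sigma))
      lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
    }
    # stabilized elpd_i = log sum(w * lik) - log sum(w)
    a <- lw + ll
    pointwise[i] <- (max(a) + log(sum(exp(a - max(a))))) -
      (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  n_bad <- sum(pareto_k > 0.7)
  structure(
    list(elpd = sum(pointwise),
         se = sqrt(N * stats::var(pointwise)),
         pointwise = pointwise,
         pareto_k = pareto_k,
         n_bad_k = n_bad),
    class = "vl_loo"
  )
}

#' Fit linear and quadratic single-exercise models
#'
#' Restricts the data to one exercise and fits two patient-level
#' varying-coefficient models with identical priors, sampler settings and
#' seed: one with intercept and linear components, one adding the quadratic
#' component. The pair feeds [compare_loo()].
#'
#' @param observations standardized-observation tibble.
#' @param exercise_id the exercise to model.
#' @param config a [model_config()]; its grouping is ignored (the fits are
#'   patient-level by construction).
#' @return a list of class `vl_model_pair` with elements `linear`,
#'   `quadratic` (both `vl_draws`) and `exercise_id`.
#' @export
fit_exercise_pair <- function(observations, exercise_id, config = model_config()) {
  obs <- observations[observations$exercise_id == exercise_id, , drop = FALSE]
  vl_assert(nrow(obs) > 0, "exercise '%s' absent from observations", exercise_id)
  vl_assert(length(unique(obs$patient_id)) >= 2,
            "exercise '%s' has fewer than 2 patients", exercise_id)
  fits <- lapply(c(2L, 3L), function(deg) {
    m <- build_model_impl(obs, config, levels = "patient", degree = deg)
    fit_growth_model(m, config)
  })
  structure(list(linear = fits[[1]], quadratic = fits[[2]],
                 exercise_id = exercise_id),
            class = "vl_model_pair")
}

#' Compare a linear/quadratic model pair by LOO
#'
#' Computes PSIS-LOO elpd for both fits of a [fit_exercise_pair()] and their
#' difference (quadratic minus linear) with a standard error from the
#' pointwise elpd differences. The quadratic model is preferred when the
#' difference is positive. A warning is attached when more than 10% of
#' observations have an unstable importance-weight tail (`k > 0.7`) in
#' either fit.
#'
#' @param pair a `vl_model_pair`.
#' @return a tibble of class `vl_loo_comparison` with one row: `exercise_id`,
#'   `elpd_linear`, `se_linear`, `elpd_quadratic`, `se_quadratic`,
#'   `elpd_diff`, `se_diff`, `preferred`, `n_bad_k`.
#' @export
compare_loo <- function(pair) {
  vl_assert(inherits(pair, "vl_model_pair"), "pair must come from fit_exercise_pair()")
  loo_l <- psis_loo(loglik_matrix(pair$linear))
  loo_q <- psis_loo(loglik_matrix(pair$quadratic))
  diff_i <- loo_q$pointwise - loo_l$pointwise
  n <- length(diff_i)
  n_bad <- max(loo_l$n_bad_k, loo_q$n_bad_k)
  if (n_bad > 0.1 * n) {
    warning(sprintf(
      "unstable importance ratios (Pareto k > 0.7) for %d of %d observations",
      n_bad, n
    ), call. = FALSE)
  }
  out <- tibble::tibble(
    exercise_id = pair$exercise_id,
    elpd_linear = loo_l$elpd, se_linear = loo_l$se,
    elpd_quadratic = loo_q$elpd, se_quadratic = loo_q$se,
    elpd_diff = sum(diff_i), se_diff = sqrt(n * stats::var(diff_i)),
    preferred = if (sum(diff_i) > 0) "quadratic" else "linear",
    n_bad_k = n_bad
  )
  class(out) <- c("vl_loo_comparison", class(out))
  out
}

#' Load-change frequencies by intervention half
#'
#' Counts, across consecutive attended sessions of each patient x exercise,
#' how often the load increased (progression), decreased (reduction) or
#' stayed put (hold), split by whether the later session falls in the first
#' half of the scheduled intervention (session index <= `n_scheduled / 2`)
#' or the second. A training plan that raises loads too early or too far
#' shows up as an excess of second-half reductions.
#'
#' @param log a raw training-log tibble with `session_index` and `load_kg`.
#' @param n_scheduled scheduled intervention length (default 24 sessions).
#' @return a tibble with columns `half`, `n_progressions`, `n_reductions`,
#'   `n_holds`, `n_pairs`.
#' @export
half_frequencies <- function(log, n_scheduled = 24) {
  mid <- n_scheduled / 2
  log <- dplyr::arrange(log, .data$patient_id, .data$exercise_id, .data$session_index)
  g <- dplyr::group_by(log, .data$patient_id, .data$exercise_id)
  g <- dplyr::mutate(g,
    change = .data$load_kg - dplyr::lag(.data$load_kg),
    later = .data$session_index
  )
  g <- dplyr::ungroup(g)
  g <- g[!is.na(g$change), , drop = FALSE]
  g$half <- ifelse(g$later <= mid, "first", "second")
  out <- dplyr::summarise(
    dplyr::group_by(g, .data$half),
    n_progressions = sum(.data$change > 1e-9),
    n_reductions = sum(.data$change < -1e-9),
    n_holds = sum(abs(.data$change) <= 1e-9),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
  # ensure both halves appear even when one has no pairs
  missing <- setdiff(c("first", "second"), out$half)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      half = missing, n_progressions = 0L, n_reductions = 0L,
      n_holds = 0L, n_pairs = 0L
    ))
  }
  dplyr::arrange(out, .data$half)
}

#' Attendance-restricted sensitivity refits
#'
#' Refits the three-level model on subsets of patients meeting increasing
#' attendance criteria and tabulates the population-level posterior
#' summaries side by side with the full-cohort fit, to check whether
#' estimates are driven by systematically low attendance.
#'
#' @param observations standardized-observation tibble.
#' @param config a [model_config()].
#' @param fractions attendance fractions to test (default 0.5 and 0.75).
#' @param n_scheduled scheduled session count the fractions refer to.
#' @param counts optional per-patient attendance counts (see
#'   [filter_attendance()]).
#' @return a tibble of population summaries with a `cohort` column
#'   (`"full"` or `"attendance>=f"`), plus attribute `n_patients`.
#' @export
sensitivity_refit <- function(observations, config = model_config(),
                              fractions = c(0.5, 0.75), n_scheduled = 24,
                              counts = NULL) {
  fit_one <- function(obs, label) {
    vl_assert(nrow(obs) > 0, "empty cohort after attendance filter '%s'", label)
    draws <- fit_growth_model(build_model(obs, config), config)
    s <- summarize_posterior(draws)
    s <- s[s$level == "population", , drop = FALSE]
    s$cohort <- label
    s$n_patients <- length(unique(obs$patient_id))
    s
  }
  out <- list(fit_one(observations, "full"))
  for (f in fractions) {
    filtered <- filter_attendance(observations, f, n_scheduled, counts)
    out[[length(out) + 1]] <- fit_one(filtered, sprintf("attendance>=%g", f))
  }
  dplyr::bind_rows(out)
}
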