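# All derived quantities operate draw-wise on a vl_draws object, so every
# summary carries full posterior uncertainty.

get_sigma <- function(draws, level, parameter) {
  if (level == "full") {
    comps <- Filter(Negate(is.null),
                    draws$sigma[c("exercise", "patient", "patient_exercise")])
    vl_assert(length(comps) > 0, "draws carry no group-level SDs")
    sq <- lapply(comps, function(s) {
      vl_assert(parameter %in% colnames(s), "parameter '%s' absent", parameter)
      s[, parameter]^2
    })
    return(sqrt(Reduce(`+`, sq)))
  }
  s <- draws$sigma[[level]]
  vl_assert(!is.null(s),
            "level '%s' absent from draws (was the model fitted with it?)", level)
  vl_assert(parameter %in% colnames(s), "parameter '%s' absent", parameter)
  s[, parameter]
}

#' 95% heterogeneity interval
#'
#' For each posterior draw, the heterogeneity interval is
#' `beta +/- 1.96 * sigma`, the normal-theory range within which a single
#' group's parameter (an exercise's, or — at the `full` level — any
#' patient-by-exercise combination's) is expected with 95% probability. The
#' per-draw endpoints are then summarized by their posterior mean and 95%
#' uncertainty interval. At the `full` level, `sigma` is the root sum of
#' squares of all group-level SDs for that parameter.
#'
#' @param draws a [vl_draws()] object.
#' @param level `"exercise"`, `"patient"`, `"patient_exercise"` or `"full"`.
#' @param parameter `"intercept"`, `"linear"` or `"quadratic"`.
#' @return a list of class `vl_heterogeneity_interval` with posterior means
#'   `lower_mean`, `upper_mean` and 95% UIs `lower_ui`, `upper_ui` of the
#'   two endpoints.
#' @export
heterogeneity_interval <- function(draws, level = "exercise",
                                   parameter = c("linear", "intercept", "quadratic")) {
  parameter <- match.arg(parameter)
  vl_assert(parameter %in% colnames(draws$beta), "parameter '%s' absent", parameter)
  beta <- draws$beta[, parameter]
  sigma <- get_sigma(draws, level, parameter)
  lo <- beta - 1.96 * sigma
  hi <- beta + 1.96 * sigma
  structure(
    list(level = level, parameter = parameter,
         lower_mean = mean(lo), upper_mean = mean(hi),
         lower_ui = ci95(lo), upper_ui = ci95(hi)),
    class = "vl_heterogeneity_interval"
  )
}

#' Between-exercise coefficient of variation
#'
#' Per draw, the ratio of the between-exercise SD to the population
#' coefficient, reported as a percentage. Summarized by the posterior median
#' and 95% UI (the ratio's distribution is typically right-skewed). Draws
#' with a population coefficient within 1e-6 of zero are excluded and
#' counted, since the ratio is unstable there.
#'
#' @param draws a [vl_draws()] object with exercise-level SDs.
#' @param parameter coefficient to assess (default `"linear"`).
#' @return a list with `median`, `lower`, `upper` (percent) and
#'   `n_excluded`.
#' @export
coefficient_of_variation <- function(draws, parameter = "linear") {
  beta <- draws$beta[, parameter]
  sigma <- get_sigma(draws, "exercise", parameter)
  keep <- abs(beta) > 1e-6
  cv <- 100 * sigma[keep] / beta[keep]
  q <- ci95(cv)
  list(median = stats::median(cv), lower = q[1], upper = q[2],
       n_excluded = sum(!keep))
}

#' Patient-to-exercise variance ratio
#'
#' Per draw, the ratio of the between-patient SD to the between-exercise SD
#' for a coefficient, answering "how much larger is the variation between
#' individuals than between exercises?". Summarized by posterior mean and
#' 95% UI; draws with a zero denominator are excluded and counted.
#'
#' @param draws a [vl_draws()] object with both SD levels.
#' @param parameter coefficient to assess (default `"linear"`).
#' @return a list with `mean`, `lower`, `upper`, `n_excluded`.
#' @export
variance_ratio <- function(draws, parameter = "linear") {
  num <- get_sigma(draws, "patient", parameter)
  den <- get_sigma(draws, "exercise", parameter)
  keep <- den > 0
  r <- num[keep] / den[keep]
  q <- ci95(r)
  list(mean = mean(r), lower = q[1], upper = q[2], n_excluded = sum(!keep))
}

#' Vertex (plateau session) of a quadratic trajectory
#'
#' For a concave trajectory `b0 + b1 t + b2 t^2` with `b2 < 0`, the session
#' at which predicted volume-load stops increasing is the vertex
#' `t* = -b1 / (2 b2)`.
#'
#' @param linear,quadratic coefficient values (vectorized).
#' @return vertex location(s) in session units.
#' @export
plateau_vertex <- function(linear, quadratic) {
  -linear / (2 * quadratic)
}

#' Monte-Carlo distribution of the plateau session
#'
#' Propagates joint posterior uncertainty in the linear and quadratic
#' components into the trajectory's vertex: `n_mc` paired values are
#' resampled with replacement from the posterior draws (pairing within a
#' draw preserved) and each pair is pushed through
#' [plateau_vertex()]. Pairs whose quadratic component is non-negative
#' define no finite plateau; by default they are excluded from the summary
#' quantiles and tallied in `prop_nonconcave` (optionally retained as
#' `+Inf`-censored). Because the resulting distribution is typically heavily
#' right-skewed, the median is the primary summary.
#'
#' @param draws a [vl_draws()] object.
#' @param scope `"population"` or an exercise label (population + that
#'   exercise's effects, summed per draw).
#' @param n_mc number of Monte-Carlo pairs (default 10000).
#' @param seed integer seed for the resampling.
#' @param nonconcave `"exclude"` (default) or `"censor"` (retain as `+Inf`;
#'   quantiles then reflect the censoring).
#' @return an object of class `vl_plateau` with the Monte-Carlo `draws`,
#'   `mean`, `median`, `sd`, `lower_ui`, `upper_ui`, `prop_nonconcave` and
#'   `scope`.
#' @export
plateau_distribution <- function(draws, scope = "population", n_mc = 10000,
                                 seed = 1L, nonconcave = c("exclude", "censor")) {
  nonconcave <- match.arg(nonconcave)
  vl_assert("quadratic" %in% colnames(draws$beta),
            "draws carry no quadratic component")
  lin <- draws$beta[, "linear"]
  quad <- draws$beta[, "quadratic"]
  if (!identical(scope, "population")) {
    vl_assert(!is.null(draws$u), "draws carry no exercise effects")
    ex_names <- dimnames(draws$u)[[2]]
    vl_assert(scope %in% ex_names, "unknown exercise '%s'", scope)
    j <- match(scope, ex_names)
    lin <- lin + draws$u[, j, "linear"]
    quad <- quad + draws$u[, j, "quadratic"]
  }
  set.seed(seed)
  idx <- sample.int(length(lin), n_mc, replace = TRUE)
  lin <- lin[idx]
  quad <- quad[idx]
  concave <- quad < 0
  if (!any(concave)) stop("no plateau identifiable: all draws non-concave", call. = FALSE)
  vertex <- plateau_vertex(lin, quad)
  if (nonconcave == "exclude") {
    vals <- vertex[concave]
  } else {
    vals <- ifelse(concave, vertex, Inf)
  }
  q <- ci95(vals)
  structure(
    list(scope = scope, draws = vals,
         mean = mean(vals), median = stats::median(vals),
         sd = stats::sd(vals[is.finite(vals)]),
         lower_ui = q[1], upper_ui = q[2],
         prop_nonconcave = mean(!concave),
         n_mc = n_mc),
    class = "vl_plateau"
  )
}

#' Per-exercise trajectory summaries
#'
#' Combines population and exercise effects (plus, under a three-level fit,
#' the mean over patients of the patient-by-exercise effects) per draw, and
#' summarizes each exercise's linear and quadratic components by posterior
#' mean, SD and 95% UI.
#'
#' @param draws a [vl_draws()] object with exercise effects.
#' @return a tibble with one row per exercise x parameter.
#' @export
exercise_trajectories <- function(draws) {
  if (is.null(draws$u)) {
    # single-exercise fit: the lone exercise equals the population
    ex <- draws$labels$exercises
    vl_assert(length(ex) == 1, "draws carry no exercise effects")
    out <- lapply(c("linear", "quadratic"), function(k) {
      q <- ci95(draws$beta[, k])
      tibble::tibble(exercise_id = ex, parameter = k,
                     mean = mean(draws$beta[, k]), sd = stats::sd(draws$beta[, k]),
                     lower = q[1], upper = q[2])
    })
    return(dplyr::bind_rows(out))
  }
  ex_names <- dimnames(draws$u)[[2]]
  pe_means <- NULL
  if (!is.null(draws$w)) {
    pe_labels <- dimnames(draws$w)[[2]]
    pe_ex <- sub("^.*:", "", pe_labels)
    pe_means <- lapply(c("linear", "quadratic"), function(k) {
      sapply(ex_names, function(e) {
        cols <- which(pe_ex == e)
        if (length(cols) == 0) rep(0, draws$n_draws)
        else rowMeans(draws$w[, cols, k, drop = FALSE])
      })
    })
    names(pe_means) <- c("linear", "quadratic")
  }
  out <- list()
  for (k in c("linear", "quadratic")) {
    for (j in seq_along(ex_names)) {
      x <- draws$beta[, k] + draws$u[, j, k]
      if (!is.null(pe_means)) x <- x + pe_means[[k]][, j]
      q <- ci95(x)
      out[[length(out) + 1]] <- tibble::tibble(
        exercise_id = ex_names[j], parameter = k,
        mean = mean(x), sd = stats::sd(x), lower = q[1], upper = q[2]
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$exercise_id, .data$parameter)
}

#' Classify patient-by-exercise responders
#'
#' The total linear slope of patient i on exercise j is
#' `b1 + u1[j] + v1[i] + w1[i,j]` per draw; the combination is labelled a
#' positive responder when the posterior median of that slope exceeds the
#' threshold (strictly: a median exactly at the threshold is negative).
#'
#' @param draws a three-level [vl_draws()] object.
#' @param threshold slope threshold (default 0).
#' @return an object of class `vl_responders`: list with `table` (per
#'   patient x exercise median slope and label), `by_exercise` (proportion
#'   positive per exercise) and `by_patient` (count of negative exercises
#'   per patient).
#' @export
classify_responders <- function(draws, threshold = 0) {
  vl_assert(!is.null(draws$w),
            "responder classification needs a three-level fit (patient-by-exercise effects)")
  pe_labels <- dimnames(draws$w)[[2]]
  pe_pat <- sub(":[^:]*$", "", pe_labels)
  pe_ex <- sub("^.*:", "", pe_labels)
  ex_names <- dimnames(draws$u)[[2]]
  pat_names <- dimnames(draws$v)[[2]]
  j_idx <- match(pe_ex, ex_names)
  i_idx <- match(pe_pat, pat_names)
  med <- numeric(length(pe_labels))
  for (q in seq_along(pe_labels)) {
    slope <- draws$beta[, "linear"] + draws$u[, j_idx[q], "linear"] +
      draws$v[, i_idx[q], "linear"] + draws$w[, q, "linear"]
    med[q] <- stats::median(slope)
  }
  tab <- tibble::tibble(
    patient_id = pe_pat, exercise_id = pe_ex,
    median_slope = med, positive = med > threshold
  )
  by_exercise <- dplyr::summarise(
    dplyr::group_by(tab, .data$exercise_id),
    prop_positive = mean(.data$positive), n = dplyr::n(), .groups = "drop"
  )
  by_patient <- dplyr::summarise(
    dplyr::group_by(tab, .data$patient_id),
    n_negative = sum(!.data$positive), n_exercises = dplyr::n(), .groups = "drop"
  )
  structure(list(table = tab, by_exercise = by_exercise,
                 by_patient = by_patient, threshold = threshold),
            class = "vl_responders")
}

#' Within-individual variability of exercise slopes
#'
#' For each patient, the SD across exercises of the posterior-median total
#' linear slopes measures how unevenly that patient progressed across
#' exercises. Reports the cohort median and range of those SDs, and the
#' Pearson correlation (with Fisher-transform 95% CI) between a patient's
#' spread and their mean progression across exercises.
#'
#' @param draws a three-level [vl_draws()] object.
#' @return a list with `per_patient` (tibble: `patient_id`, `sd_slope`,
#'   `mean_slope`, `n_exercises`), `median`, `range`, and `correlation`
#'   (list `r`, `lower`, `upper`).
#' @export
within_individual_variability <- function(draws) {
  resp <- classify_responders(draws, threshold = 0)
  tab <- resp$table
  per <- dplyr::summarise(
    dplyr::group_by(tab, .data$patient_id),
    sd_slope = stats::sd(.data$median_slope),
    mean_slope = mean(.data$median_slope),
    n_exercises = dplyr::n(), .groups = "drop"
  )
  single <- per$n_exercises < 2
  if (any(single)) {
    warning(sprintf("excluding %d patient(s) with a single exercise", sum(single)),
            call. = FALSE)
    per <- per[!single, , drop = FALSE]
  }
  vl_assert(nrow(per) >= 3, "too few patients with >= 2 exercises")
  r <- stats::cor(per$sd_slope, per$mean_slope)
  n <- nrow(per)
  zf <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(zf + c(-1.96, 1.96) * se)
  list(
    per_patient = per,
    median = stats::median(per$sd_slope),
    range = range(per$sd_slope),
    correlation = list(r = r, lower = ci[1], upper = ci[2])
  )
}
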