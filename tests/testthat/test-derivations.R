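test_that("heterogeneity interval matches the plug-in construction", {
  d <- degenerate_draws(n = 150)
  hi <- heterogeneity_interval(d, "exercise", "linear")
  expect_equal(hi$lower_mean, 0.093 - 1.96 * 0.043, tolerance = 1e-12)
  expect_equal(hi$upper_mean, 0.093 + 1.96 * 0.043, tolerance = 1e-12)
  expect_equal(hi$lower_mean, 0.00872, tolerance = 1e-6)
  expect_equal(hi$upper_mean, 0.17728, tolerance = 1e-6)
  # zero heterogeneity: both endpoints collapse onto the population value
  d0 <- degenerate_draws(sigma_exercise = c(0, 0, 0), n = 150)
  hi0 <- heterogeneity_interval(d0, "exercise", "linear")
  expect_equal(hi0$lower_mean, 0.093)
  expect_equal(hi0$upper_mean, 0.093)
  # full level combines group SDs in quadrature
  hf <- heterogeneity_interval(d, "full", "linear")
  expect_equal(hf$upper_mean, 0.093 + 1.96 * sqrt(0.043^2 + 0.155^2),
               tolerance = 1e-12)
  # requesting an absent level errors
  d2 <- vl_draws(beta = d$beta, sigma_exercise = d$sigma$exercise)
  expect_error(heterogeneity_interval(d2, "patient", "linear"), "absent")
})

test_that("heterogeneity interval is symmetric about the population draw", {
  set.seed(4)
  n <- 500
  d <- vl_draws(
    beta = cbind(intercept = rnorm(n), linear = rnorm(n, 0.1, 0.02),
                 quadratic = rnorm(n, -0.002, 0.001)),
    sigma_exercise = cbind(intercept = abs(rnorm(n)), linear = abs(rnorm(n, 0.04, 0.01)),
                           quadratic = abs(rnorm(n, 0.002, 0.001)))
  )
  hi <- heterogeneity_interval(d, "exercise", "linear")
  expect_equal(hi$lower_mean + hi$upper_mean, 2 * mean(d$beta[, "linear"]),
               tolerance = 1e-12)
})

test_that("coefficient of variation and variance ratio match hand arithmetic", {
  d <- degenerate_draws(n = 150)
  cv <- coefficient_of_variation(d, "linear")
  expect_equal(cv$median, 100 * 0.043 / 0.093, tolerance = 1e-10)
  expect_equal(cv$median, 46.2, tolerance = 0.05)
  d0 <- degenerate_draws(sigma_exercise = c(0, 0, 0), n = 150)
  expect_equal(coefficient_of_variation(d0, "linear")$median, 0)
  # near-zero population draws are excluded and counted
  db <- degenerate_draws(beta = c(0, 0, 0), n = 150)
  expect_equal(coefficient_of_variation(db, "linear")$n_excluded, 150)

  vr <- variance_ratio(d, "linear")
  expect_equal(vr$mean, 0.155 / 0.043, tolerance = 1e-10)
  expect_equal(round(vr$mean, 1), 3.6)
  dq <- degenerate_draws(sigma_exercise = c(0.047, 0.043, 0.002),
                         sigma_patient = c(1.007, 0.155, 0.008), n = 150)
  expect_equal(round(variance_ratio(dq, "quadratic")$mean, 1), 4.0)
})

test_that("reciprocal variance ratios multiply to one per draw", {
  set.seed(9)
  n <- 300
  a <- abs(rnorm(n, 0.15, 0.02))
  b <- abs(rnorm(n, 0.04, 0.01))
  d_ab <- vl_draws(beta = cbind(intercept = rep(0, n), linear = rep(1, n)),
                   sigma_exercise = cbind(intercept = b, linear = b),
                   sigma_patient = cbind(intercept = a, linear = a))
  d_ba <- vl_draws(beta = d_ab$beta,
                   sigma_exercise = cbind(intercept = a, linear = a),
                   sigma_patient = cbind(intercept = b, linear = b))
  r_ab <- vltraj:::get_sigma(d_ab, "patient", "linear") /
    vltraj:::get_sigma(d_ab, "exercise", "linear")
  r_ba <- vltraj:::get_sigma(d_ba, "patient", "linear") /
    vltraj:::get_sigma(d_ba, "exercise", "linear")
  expect_equal(r_ab * r_ba, rep(1, n), tolerance = 1e-12)
})

test_that("plateau vertex matches hand arithmetic and the printed interval", {
  expect_equal(plateau_vertex(0.093, -0.002), 23.25)
  expect_equal(plateau_vertex(0.1, -0.05), 1.0)
  d <- degenerate_draws(n = 150)
  p <- plateau_distribution(d, n_mc = 1000, seed = 1)
  expect_equal(p$median, 23.25)
  expect_equal(p$prop_nonconcave, 0)
  # linear component identically zero: vertex at the origin
  d0 <- degenerate_draws(beta = c(0.049, 0, -0.002), n = 150)
  expect_equal(plateau_distribution(d0, n_mc = 500, seed = 1)$median, 0)
  # all draws convex: no plateau
  dpos <- degenerate_draws(beta = c(0, 0.1, 0.01), n = 150)
  expect_error(plateau_distribution(dpos, n_mc = 100, seed = 1), "no plateau")
})

test_that("plateau median is invariant to joint positive scaling", {
  set.seed(6)
  n <- 400
  lin <- rnorm(n, 0.09, 0.02)
  quad <- rnorm(n, -0.002, 0.0008)
  mk <- function(s) vl_draws(beta = cbind(intercept = rep(0, n),
                                          linear = s * lin, quadratic = s * quad))
  p1 <- plateau_distribution(mk(1), n_mc = 5000, seed = 3)
  p2 <- plateau_distribution(mk(7.3), n_mc = 5000, seed = 3)
  expect_equal(p1$median, p2$median, tolerance = 1e-9)
  expect_equal(p1$prop_nonconcave, p2$prop_nonconcave)
})

test_that("vertex equals the grid-search argmax for concave trajectories", {
  set.seed(12)
  grid <- seq(0, 60, by = 0.01)
  for (i in 1:20) {
    b1 <- runif(1, 0.02, 0.2)
    b2 <- -runif(1, 0.002, 0.02)
    curve_vals <- b1 * grid + b2 * grid^2
    brute <- grid[which.max(curve_vals)]
    expect_lt(abs(plateau_vertex(b1, b2) - brute), 0.01 + 1e-9)
  }
})

test_that("non-concave draws are tallied and optionally censored", {
  set.seed(7)
  n <- 1000
  quad <- c(rep(-0.002, 900), rep(0.001, 100))
  d <- vl_draws(beta = cbind(intercept = rep(0, n), linear = rep(0.09, n),
                             quadratic = quad))
  p <- plateau_distribution(d, n_mc = 20000, seed = 2)
  expect_equal(p$prop_nonconcave, 0.1, tolerance = 0.02)
  expect_true(all(is.finite(p$draws)))
  pc <- plateau_distribution(d, n_mc = 20000, seed = 2, nonconcave = "censor")
  expect_true(any(!is.finite(pc$draws)))
})

test_that("exercise trajectories collapse to the population when effects vanish", {
  n <- 150
  u <- array(0, c(n, 3, 3), dimnames = list(NULL, c("a", "b", "c"),
                                            c("intercept", "linear", "quadratic")))
  d <- degenerate_draws(n = n)
  d$u <- u
  tr <- exercise_trajectories(d)
  expect_equal(unique(tr$mean[tr$parameter == "linear"]), 0.093)
  expect_equal(unique(tr$mean[tr$parameter == "quadratic"]), -0.002)
})

test_that("injected exercise slope ordering is recovered by the fit", {
  cfg <- small_cohort(seed = 23, n_patients = 16, n_exercises = 4,
                      n_sessions = 12,
                      sd_exercise = c(0.05, 0.2, 0.001),
                      residual_sd = 0.15)
  sim <- generate_standardized(cfg)
  mcfg <- fast_config(seed = 3)
  fit <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
  tr <- exercise_trajectories(fit)
  fitted_lin <- tr$mean[tr$parameter == "linear"]
  names(fitted_lin) <- tr$exercise_id[tr$parameter == "linear"]
  truth <- sim$truth$u[, "linear"]
  expect_equal(order(fitted_lin[names(truth)]), order(truth))
})

test_that("responder classification follows the posterior-median sign", {
  n <- 200
  mk_arr <- function(labels, vals) {
    arr <- array(rep(vals, each = n), c(n, length(labels), 3),
                 dimnames = list(NULL, labels, c("intercept", "linear", "quadratic")))
    arr
  }
  d <- degenerate_draws(n = n)
  d$u <- array(0, c(n, 2, 3), dimnames = list(NULL, c("e1", "e2"),
                                              c("intercept", "linear", "quadratic")))
  d$v <- array(0, c(n, 2, 3), dimnames = list(NULL, c("p1", "p2"),
                                              c("intercept", "linear", "quadratic")))
  w <- array(0, c(n, 4, 3),
             dimnames = list(NULL, c("p1:e1", "p1:e2", "p2:e1", "p2:e2"),
                             c("intercept", "linear", "quadratic")))
  w[, "p2:e2", 2] <- -0.2   # pushes that slope to 0.093 - 0.2 < 0
  w[, "p2:e1", 2] <- -0.093 # median exactly at threshold -> negative label
  d$w <- w
  r <- classify_responders(d)
  tab <- r$table
  expect_true(tab$positive[tab$patient_id == "p1" & tab$exercise_id == "e1"])
  expect_false(tab$positive[tab$patient_id == "p2" & tab$exercise_id == "e2"])
  expect_false(tab$positive[tab$patient_id == "p2" & tab$exercise_id == "e1"])
  expect_equal(r$by_exercise$prop_positive[r$by_exercise$exercise_id == "e1"], 0.5)
  expect_equal(r$by_patient$n_negative[r$by_patient$patient_id == "p2"], 2L)
  # two-level draws cannot be classified
  d2 <- degenerate_draws(n = n)
  expect_error(classify_responders(d2), "three-level")
})

test_that("raising the threshold never adds positive responders", {
  cfg <- small_cohort(seed = 29, n_patients = 12, n_exercises = 3, n_sessions = 10)
  sim <- generate_standardized(cfg)
  mcfg <- fast_config(seed = 8)
  fit <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
  counts <- vapply(c(-0.05, 0, 0.05, 0.1), function(th) {
    sum(classify_responders(fit, th)$table$positive)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classified positive fraction tracks the generating truth", {
  cfg <- small_cohort(seed = 37, n_patients = 30, n_exercises = 6,
                      n_sessions = 14, residual_sd = 0.1)
  sim <- generate_standardized(cfg)
  truth <- sim$truth
  J <- length(cfg$exercise_names)
  true_slopes <- outer(truth$v[, "linear"], truth$u[, "linear"], `+`) +
    truth$beta[2] +
    matrix(truth$w[, "linear"], nrow = cfg$n_patients, ncol = J, byrow = TRUE)
  mcfg <- fast_config(seed = 2)
  fit <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
  r <- classify_responders(fit)
  expect_lt(abs(mean(r$table$positive) - mean(true_slopes > 0)), 0.05)
})

test_that("within-individual spread matches hand-computed SDs", {
  n <- 150
  d <- degenerate_draws(n = n)
  d$u <- array(0, c(n, 4, 3), dimnames = list(NULL, paste0("e", 1:4),
                                              c("intercept", "linear", "quadratic")))
  d$v <- array(0, c(n, 3, 3), dimnames = list(NULL, paste0("p", 1:3),
                                              c("intercept", "linear", "quadratic")))
  labels <- as.vector(t(outer(paste0("p", 1:3), paste0("e", 1:4), paste, sep = ":")))
  w <- array(0, c(n, 12, 3), dimnames = list(NULL, labels,
                                             c("intercept", "linear", "quadratic")))
  # patient p1 gets total slopes 0.1, 0.2, 0.3, 0.4; others flat
  shifts <- c(0.1, 0.2, 0.3, 0.4) - 0.093
  for (j in 1:4) w[, paste0("p1:e", j), 2] <- shifts[j]
  d$w <- w
  wiv <- within_individual_variability(d)
  p1 <- wiv$per_patient[wiv$per_patient$patient_id == "p1", ]
  expect_equal(p1$sd_slope, stats::sd(c(0.1, 0.2, 0.3, 0.4)), tolerance = 1e-12)
  expect_equal(p1$sd_slope, 0.1291, tolerance = 1e-4)
  # identical slopes across exercises -> zero spread
  p2 <- wiv$per_patient[wiv$per_patient$patient_id == "p2", ]
  expect_equal(p2$sd_slope, 0)
})

test_that("within-individual spread vanishes as interaction and noise shrink", {
  sd_for <- function(sd_pe, res) {
    cfg <- small_cohort(seed = 43, n_patients = 10, n_exercises = 4,
                        n_sessions = 10,
                        sd_exercise = c(0, 0, 0),
                        sd_patient_exercise = c(0, sd_pe, 0),
                        residual_sd = res)
    sim <- generate_standardized(cfg)
    mcfg <- fast_config(seed = 5)
    fit <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
    within_individual_variability(fit)$median
  }
  expect_lt(sd_for(0, 0.02), 0.25 * sd_for(0.15, 0.3))
})
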