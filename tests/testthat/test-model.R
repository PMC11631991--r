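test_that("prior modes produce the documented scales", {
  wi <- default_priors()
  expect_equal(wi$beta_scale, c(1, 1, 1))
  expect_equal(unname(wi$sd_scale), rep(1, 4))
  di <- default_priors("diffuse")
  expect_equal(di$beta_scale, c(10, 10, 10))
  expect_equal(unname(di$sd_scale), rep(10, 4))
  us <- default_priors("user_supplied",
                       beta_location = c(0, 0.1, 0),
                       beta_scale = c(1, 0.05, 0.01),
                       sd_scale = c(exercise = 0.5, patient = 1,
                                    patient_exercise = 0.5, residual = 1))
  expect_equal(us$beta_location[2], 0.1)
  expect_equal(us$beta_scale[2], 0.05)
  expect_error(default_priors("user_supplied", beta_location = c(0, 0, 0)),
               "beta_scale")
  expect_error(
    default_priors("user_supplied", beta_location = c(0, 0, 0),
                   beta_scale = c(1, 1, 1), sd_scale = c(exercise = 1)),
    "patient"
  )
  expect_error(
    default_priors("user_supplied", beta_location = c(0, 0, 0),
                   beta_scale = c(1, -1, 1),
                   sd_scale = c(exercise = 1, patient = 1,
                                patient_exercise = 1, residual = 1)),
    "positive"
  )
})

test_that("user-supplied priors pass through to the sampler data", {
  us <- default_priors("user_supplied",
                       beta_location = c(0, 0.1, 0),
                       beta_scale = c(1, 0.05, 1),
                       sd_scale = c(exercise = 2, patient = 3,
                                    patient_exercise = 4, residual = 5))
  cfg <- model_config(priors = us)
  sim <- generate_standardized(small_cohort(seed = 2, n_patients = 4,
                                            n_exercises = 2, n_sessions = 5))
  m <- build_model(sim$observations, cfg)
  expect_equal(m$data$beta_loc[2], 0.1)
  expect_equal(m$data$beta_scale[2], 0.05)
  expect_equal(m$data$scale_u, 2)
  expect_equal(m$data$scale_v, 3)
  expect_equal(m$data$scale_w, 4)
  expect_equal(m$data$scale_res, 5)
})

test_that("model specification honours the grouping contract", {
  sim <- generate_standardized(small_cohort(seed = 2, n_patients = 4,
                                            n_exercises = 2, n_sessions = 5))
  m3 <- build_model(sim$observations, model_config())
  expect_true(grepl("w\\[", m3$code))
  m2 <- build_model(sim$observations, model_config(grouping = "two_level"))
  expect_false(grepl("w\\[", m2$code))
  # quadratic design row for t = 3
  i <- which(sim$observations$t == 3)[1]
  expect_equal(unname(m3$data$X[i, ]), c(1, 3, 9))
  # single-exercise data with a three-level request is refused with advice
  single <- sim$observations[sim$observations$exercise_id == "ex1", ]
  expect_error(build_model(single, model_config()), "two_level")
  # under two_level grouping a lone exercise folds into the population
  m1 <- build_model(single, model_config(grouping = "two_level"))
  expect_false("exercise" %in% m1$levels)
  expect_equal(m1$labels$exercises, "ex1")
  # specification survives serialization unchanged
  expect_identical(unserialize(serialize(m3, NULL)), m3)
})

test_that("posterior summaries match analytic oracles", {
  const <- degenerate_draws(n = 150)
  s <- summarize_posterior(const)
  lin <- s[s$level == "population" & s$parameter == "linear", ]
  expect_equal(lin$mean, 0.093)
  expect_equal(lin$sd, 0)
  expect_equal(c(lin$lower, lin$upper), c(0.093, 0.093))
  # Monte-Carlo quantile oracle on a standard normal sample
  set.seed(123)
  x <- stats::rnorm(1e5)
  d <- vl_draws(beta = cbind(intercept = x, linear = x))
  s2 <- summarize_posterior(d)
  expect_lt(abs(s2$lower[1] - (-1.96)), 0.02)
  expect_lt(abs(s2$upper[1] - 1.96), 0.02)
  expect_error(summarize_posterior(degenerate_draws(n = 50)), "100")
})

test_that("a noise-free cohort is recovered nearly exactly", {
  cfg <- generator_config(
    n_patients = 10, exercise_names = c("a", "b", "c"), n_sessions = 8,
    population_beta = c(0, 0.1, 0),
    sd_exercise = c(0, 0, 0), sd_patient = c(0, 0, 0),
    sd_patient_exercise = c(0, 0, 0), residual_sd = 0.01,
    attendance_rate = 1, seed = 8
  )
  sim <- generate_standardized(cfg)
  mcfg <- fast_config(seed = 4)
  fit <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
  s <- summarize_posterior(fit)
  expect_lt(abs(s$mean[s$parameter == "linear" & s$level == "population"] - 0.1),
            0.005)
  # all variance-component posteriors concentrate near zero
  sds <- s[grepl("^sd_", s$level) & s$level != "sd_residual", ]
  expect_lt(max(sds$mean), 0.05)
})

test_that("fits are reproducible for a fixed seed and shift with diffuse priors", {
  sim <- generate_standardized(small_cohort(seed = 14, n_patients = 12,
                                            n_exercises = 3, n_sessions = 10))
  mcfg <- fast_config(seed = 7)
  f1 <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
  f2 <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
  expect_identical(f1$beta, f2$beta)
  # diffuse priors barely move the population means (data dominate)
  dcfg <- fast_config(seed = 7, priors = default_priors("diffuse"))
  f3 <- fit_growth_model(build_model(sim$observations, dcfg), dcfg)
  expect_lt(abs(mean(f1$beta[, "linear"]) - mean(f3$beta[, "linear"])), 0.02)
})

test_that("population summaries are stable under patient relabelling", {
  sim <- generate_standardized(small_cohort(seed = 15, n_patients = 10,
                                            n_exercises = 3, n_sessions = 8))
  obs <- sim$observations
  relabel <- stats::setNames(sprintf("Z%02d", 10:1), sort(unique(obs$patient_id)))
  obs2 <- obs
  obs2$patient_id <- unname(relabel[obs$patient_id])
  mcfg <- fast_config(seed = 9)
  f1 <- fit_growth_model(build_model(obs, mcfg), mcfg)
  f2 <- fit_growth_model(build_model(obs2, mcfg), mcfg)
  mcse <- stats::sd(f1$beta[, "linear"]) / sqrt(coda::effectiveSize(
    coda::as.mcmc(f1$beta[, "linear"])))
  expect_lt(abs(mean(f1$beta[, "linear"]) - mean(f2$beta[, "linear"])),
            8 * mcse + 0.01)
})

test_that("longer follow-up and more patients contract the posterior", {
  mcfg <- fast_config(seed = 6)
  sd_of <- function(n_pat, n_ses, seed) {
    sim <- generate_standardized(small_cohort(seed = seed, n_patients = n_pat,
                                              n_exercises = 4,
                                              n_sessions = n_ses))
    f <- fit_growth_model(build_model(sim$observations, mcfg), mcfg)
    stats::sd(f$beta[, "linear"])
  }
  expect_lt(sd_of(24, 16, 101), sd_of(12, 8, 101))
})

test_that("draws persist to a columnar table with metadata", {
  d <- degenerate_draws(n = 120)
  path <- tempfile(fileext = ".csv")
  write_draws(d, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 120)
  expect_true(all(c("beta_linear", "sigma_exercise_linear",
                    "sigma_patient_quadratic", "sigma_residual") %in% names(tab)))
  expect_equal(unique(tab$beta_linear), 0.093)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$n_draws, 120)
})
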