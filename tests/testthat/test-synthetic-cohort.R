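test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_patients = 0), ">= 1")
  expect_error(simulation_config(vas1_range = c(-1, 10)), "within \\[0, 10\\]")
  expect_error(simulation_config(noise_sd = -0.1), ">= 0")
  expect_error(simulation_config(covariate_effects = rep(0, 13)), "length 14")
})

test_that("same seed reproduces the cohort and covariates exactly", {
  cfg <- simulation_config(n_patients = 30, seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(simulate_covariates(c1), simulate_covariates(c2))
})

test_that("noise-free trajectories lie exactly on their generating curves", {
  cfg <- simulation_config(n_patients = 25, noise_sd = 0, rounding = 0, seed = 9)
  cohort <- simulate_cohort(cfg)
  for (p in cohort$patients) {
    tp <- p$true_params
    expect_equal(p$trajectory$vas,
                 logistic_curve(1:10, tp[["K"]], tp[["a"]], tp[["b"]]),
                 tolerance = 1e-12)
  }
})

test_that("observed scores respect the scale and the recording resolution", {
  cohort <- simulate_cohort(simulation_config(n_patients = 60, seed = 2))
  for (p in cohort$patients) {
    v <- p$trajectory$vas
    expect_true(all(v >= 0 & v <= 10))
    expect_equal(v, round(v / 0.1) * 0.1, tolerance = 1e-9)
    expect_identical(p$trajectory$sessions, as.numeric(1:10))
  }
})

test_that("baseline VAS distribution matches its configured target", {
  cohort <- simulate_cohort(simulation_config(n_patients = 2000, seed = 13))
  first <- vapply(cohort_trajectories(cohort), function(t) t$vas[1], 0)
  expect_lt(abs(median(first) - 6.8), 0.2)
  # the truncation bound is exact on the noise-free latent baseline
  clean <- simulate_cohort(simulation_config(n_patients = 500, noise_sd = 0,
                                             rounding = 0, seed = 13))
  first_clean <- vapply(cohort_trajectories(clean), function(t) t$vas[1], 0)
  expect_gte(min(first_clean), 3)
  expect_lte(max(first_clean), 10)
})

test_that("the cohort mixes S-shaped and near-linear remission courses", {
  cohort <- simulate_cohort(simulation_config(seed = 4))
  line_r2 <- vapply(cohort$patients, function(p) {
    tp <- p$true_params
    y <- logistic_curve(1:10, tp[["K"]], tp[["a"]], tp[["b"]])
    x <- 1:10
    1 - sum(stats::lm.fit(cbind(1, x), y)$residuals^2) / sum((y - mean(y))^2)
  }, 0)
  expect_gt(sum(line_r2 > 0.98), 0)  # near-linear courses present
  expect_gt(sum(line_r2 < 0.90), 0)  # clearly sigmoid courses present
})

test_that("ground-truth efficacy label uses a strict MCSD decline", {
  # flat curve: never effective
  flat <- structure(list(true_params = c(K = 5, a = 0, b = 0)),
                    class = "synthetic_patient")
  expect_false(true_outcome_label(flat))
  # steep decline: effective
  steep <- structure(list(true_params = c(K = 8, a = -3, b = 1.5)),
                     class = "synthetic_patient")
  expect_true(true_outcome_label(steep))
  # decline of exactly the MCSD is NOT effective (strict inequality):
  # construct b = 0 curve shifted by choosing K so the decline is exactly 1.2
  # via a linear-in-K property of the curve difference
  tp <- c(K = 8, a = -3, b = 0.6)
  d <- logistic_curve(1, tp[["K"]], tp[["a"]], tp[["b"]]) -
    logistic_curve(10, tp[["K"]], tp[["a"]], tp[["b"]])
  K_exact <- unname(8 * 1.2 / d)  # decline scales linearly with K
  exact <- structure(list(true_params = c(K = K_exact, a = -3, b = 0.6)),
                     class = "synthetic_patient")
  expect_false(true_outcome_label(exact))
  expect_true(true_outcome_label(exact, mcsd = 1.2 - 1e-9))
})

test_that("null covariate effects give the intercept-implied prevalence", {
  cfg <- simulation_config(n_patients = 4000, seed = 21,
                           covariate_effects = rep(0, 14),
                           outcome_intercept = stats::qlogis(0.65))
  cov <- simulate_covariates(4000, cfg)
  expect_lt(abs(mean(cov$outcome) - 0.65), 0.025)
})

test_that("a dominant positive coefficient makes the outcome rate monotone", {
  eff <- rep(0, 14); eff[1] <- 2.5
  cfg <- simulation_config(n_patients = 2000, seed = 8,
                           covariate_effects = eff)
  cov <- simulate_covariates(2000, cfg)
  q <- cut(cov$sagittal_diameter_protrusion,
           stats::quantile(cov$sagittal_diameter_protrusion, 0:5 / 5),
           include.lowest = TRUE)
  rates <- tapply(cov$outcome, q, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("covariate table has the 14 documented columns and recorded link", {
  cfg <- simulation_config(n_patients = 10, seed = 5)
  cov <- simulate_covariates(10, cfg)
  expect_named(cov, c("patient_id",
                      "sagittal_diameter_protrusion",
                      "degeneration_surgical_segment", "age",
                      "time_symptom_to_operation",
                      "degeneration_adjacent_segment", "gender",
                      paste0("covariate_", sprintf("%02d", 7:14)), "outcome"))
  link <- attr(cov, "link")
  expect_length(link$coefficients, 14)
  expect_true(all(cov$age >= 17 & cov$age <= 87))
  expect_true(all(cov$gender %in% 0:1))
})
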