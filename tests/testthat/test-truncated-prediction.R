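test_that("truncated fits delegate correctly and validate m", {
  cs <- consistent_trajectory(8, 4)
  # m = 10 equals the full fit
  full <- fit_patient(cs$traj)
  m10 <- fit_truncated(cs$traj, 10)
  expect_equal(m10$a, full$a, tolerance = 1e-8)
  expect_equal(m10$b, full$b, tolerance = 1e-8)
  # noise-free S-curve truncated mid-course still extrapolates the truth
  m5 <- fit_truncated(cs$traj, 5)
  expect_equal(predict_final_vas(m5),
               logistic_curve(10, cs$K, cs$a, cs$b), tolerance = 1e-3)
  expect_error(fit_truncated(cs$traj, 1), "at least 2")
  expect_error(fit_truncated(cs$traj, 11), "exceeds")
})

test_that("final-VAS prediction clips to the scale", {
  cs <- consistent_trajectory(8, 4)
  fit <- fit_patient(cs$traj)
  expect_equal(predict_final_vas(fit),
               logistic_curve(10, fit$K, fit$a, fit$b), tolerance = 1e-12)
  # b = 0 constant fit predicts the constant
  flat <- fit_patient(vas_trajectory("p", 1:10, rep(3, 10)))
  expect_equal(predict_final_vas(flat), 3, tolerance = 1e-6)
  # saturated fit predicts the asymptote, clip inactive
  sat <- structure(list(K = 10, lower = 0, a = -20, b = 0), class = "curve_fit")
  expect_equal(predict_final_vas(sat), 10, tolerance = 1e-8)
})

test_that("MCSD boundary conventions: strict for effectiveness, inclusive for remission", {
  expect_true(classify_effectiveness(1.3))
  expect_false(classify_effectiveness(1.2))   # exactly the MCSD: not effective
  expect_false(classify_effectiveness(0))
  expect_true(remission_success(4.0, 5.0))
  expect_true(remission_success(4.0, 5.2))    # exactly the MCSD apart: success
  expect_false(remission_success(4.0, 6.0))
})

test_that("success tables conserve counts and reproduce their own records", {
  cohort <- simulate_cohort(simulation_config(n_patients = 40, seed = 17))
  an <- build_success_tables(cohort)
  n <- attr(an$effectiveness, "n_patients")
  expect_equal(n, 40)
  expect_identical(an$effectiveness$m, 2:9)
  expect_true(all(an$effectiveness$success + an$effectiveness$failure == n))
  expect_true(all(an$remission$success + an$remission$failure == n))
  # recompute from raw records
  for (i in seq_len(nrow(an$effectiveness))) {
    m <- an$effectiveness$m[i]
    rec <- an$records[an$records$m == m, ]
    expect_equal(sum(rec$effectiveness_success), an$effectiveness$success[i])
    expect_equal(sum(rec$remission_success), an$remission$success[i])
  }
  # both declines are anchored at the measured first-session score
  firsts <- vapply(cohort_trajectories(cohort), function(t) t$vas[1], 0)
  names(firsts) <- vapply(cohort$patients,
                          function(p) p$trajectory$patient_id, "")
  expect_equal(an$records$predicted_decline + an$records$predicted_final,
               unname(firsts[an$records$patient_id]))
  expect_equal(an$records$actual_decline + an$records$actual_final,
               unname(firsts[an$records$patient_id]))
})

test_that("noise-free cohorts are predicted perfectly from three sessions on", {
  cfg <- simulation_config(n_patients = 25, noise_sd = 0, rounding = 0, seed = 31)
  an <- build_success_tables(simulate_cohort(cfg))
  sub <- an$effectiveness[an$effectiveness$m >= 3, ]
  expect_true(all(sub$success_pct == 100))
  sub_r <- an$remission[an$remission$m >= 3, ]
  expect_true(all(sub_r$success_pct == 100))
})

test_that("incomplete trajectories are excluded with a warning", {
  trajs <- cohort_trajectories(simulate_cohort(simulation_config(n_patients = 5, seed = 3)))
  short <- vas_trajectory("short", 1:8, trajs[[1]]$vas[1:8])
  expect_warning(an <- build_success_tables(c(trajs, list(short))),
                 "without a complete")
  expect_equal(attr(an$effectiveness, "n_patients"), 5)
})

test_that("chi-square equals the Pearson formula, no continuity correction", {
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  res <- chi_square_test(tab)
  expect_equal(res$chi2, pearson_chi2(tab), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, stats::pchisq(res$chi2, 1, lower.tail = FALSE))
  # equal proportions: statistic 0, p 1
  flat <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square_test(flat)$chi2, 0)
  expect_equal(chi_square_test(flat)$p, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "degenerate")
  expect_error(chi_square_test(matrix(1:2, 1)), "at least 2 rows")
})

test_that("pooled comparisons partition lengths and match the direct formula", {
  # success table built from printed-style counts over n = 142
  rec <- data.frame(m = rep(2:9, each = 142),
                    patient_id = rep(sprintf("P%03d", 1:142), times = 8))
  succ <- c(87, 105, 110, 120, 121, 114, 119, 128)
  rec$effectiveness_success <- unlist(lapply(seq_along(succ), function(i) {
    c(rep(TRUE, succ[i]), rep(FALSE, 142 - succ[i]))
  }))
  tab <- remcurve:::success_table(rec, "effectiveness_success")
  cmp <- pooled_group_comparison(tab, list("2-4" = 2:4, "5-9" = 5:9))
  pooled <- matrix(c(sum(succ[1:3]), 3 * 142 - sum(succ[1:3]),
                     sum(succ[4:8]), 5 * 142 - sum(succ[4:8])),
                   2, byrow = TRUE)
  expect_equal(unname(cmp$contingency), pooled)
  expect_equal(cmp$chi2, pearson_chi2(pooled), tolerance = 1e-12)
  expect_equal(cmp$df, 1)

  # three groups emit consecutive pairwise 2x2 contrasts
  cmp3 <- pooled_group_comparison(tab, list("2-4" = 2:4, "5-7" = 5:7, "8-9" = 8:9))
  expect_length(cmp3$pairwise, 2)
  expect_equal(cmp3$pairwise[[1]]$chi2,
               pearson_chi2(cmp3$contingency[1:2, ]), tolerance = 1e-12)

  # a non-partition or a single group is a configuration error
  expect_error(pooled_group_comparison(tab, list(all = 2:9)), "at least 2")
  expect_error(pooled_group_comparison(tab, list(a = 2:4, b = 4:9)), "partition")
  expect_error(pooled_group_comparison(tab, list(a = 2:4, b = 5:8)), "partition")
})
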