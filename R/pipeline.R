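# End-to-end orchestration and file formats: simulate a cohort, fit every
# remission curve, run the truncated-course predictive analysis, train and
# evaluate the boosting classifier, and write a reproducible report.

#' Pipeline configuration
#'
#' @param simulation A [simulation_config()].
#' @param gbm A [gbm_config()].
#' @param lengths Treatment lengths for the truncated analysis, a subset
#'   of 2..9 (default all).
#' @param mcsd Minimal clinically significant difference, VAS points
#'   (default 1.2); drives the asymptote rule and both success
#'   classifications.
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param verbose Emit progress messages (default `TRUE`).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            gbm = gbm_config(),
                            lengths = 2:9, mcsd = 1.2,
                            out_dir = tempfile("remcurve-run-"),
                            verbose = TRUE) {
  if (mcsd <= 0) stop("`mcsd` must be positive", call. = FALSE)
  lengths <- sort(unique(as.integer(lengths)))
  if (!all(lengths %in% 2:9)) stop("`lengths` must be a subset of 2..9", call. = FALSE)
  structure(
    list(simulation = simulation, gbm = gbm, lengths = lengths,
         mcsd = mcsd, out_dir = out_dir, verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

#' Read VAS trajectories from CSV
#'
#' Expects columns `patient_id`, `session`, `vas` in long format; rows are
#' grouped by patient and sorted by session. Violations of the trajectory
#' invariants (non-numeric or out-of-range VAS, duplicated
#' patient/session pairs) raise errors naming the offending file row.
#'
#' @param path CSV file path.
#' @return List of [vas_trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "session", "vas")
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  vas <- suppressWarnings(as.numeric(df$vas))
  bad <- which(is.na(vas))
  if (length(bad) > 0L) {
    stop("non-numeric VAS at file row ", bad[1L] + 1L, call. = FALSE)
  }
  bad <- which(vas < 0 | vas > 10)
  if (length(bad) > 0L) {
    stop("VAS out of [0, 10] at file row ", bad[1L] + 1L, call. = FALSE)
  }
  dup <- which(duplicated(df[c("patient_id", "session")]))
  if (length(dup) > 0L) {
    stop("duplicated (patient_id, session) at file row ", dup[1L] + 1L,
         call. = FALSE)
  }
  ids <- unique(df$patient_id)
  lapply(ids, function(id) {
    sub <- df[df$patient_id == id, ]
    sub <- sub[order(sub$session), ]
    vas_trajectory(id, sub$session, sub$vas)
  })
}

#' Write VAS trajectories to CSV
#'
#' Long format with columns `patient_id`, `session`, `vas`; the inverse
#' of [read_trajectories()].
#'
#' @param trajectories List of [vas_trajectory()] or a
#'   `"synthetic_cohort"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "synthetic_cohort")) {
    trajectories <- cohort_trajectories(trajectories)
  }
  df <- do.call(rbind, lapply(trajectories, function(t) {
    data.frame(patient_id = t$patient_id, session = t$sessions, vas = t$vas,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

ordinal_label <- function(m) {
  suffix <- function(k) {
    if (k %% 100 %in% 11:13) return("th")
    switch(as.character(k %% 10), "1" = "st", "2" = "nd", "3" = "rd", "th")
  }
  vapply(m, function(k) sprintf("1st-%d%s", k, suffix(k)), "")
}

#' Write a success table to CSV
#'
#' One row per treatment length, in the count/percent presentation of the
#' study tables: columns `length` (e.g. `1st-9th`), `success_count`,
#' `success_pct`, `failure_count`, `failure_pct`, percentages to one
#' decimal (half-up). The success/failure counts are checked to sum to
#' the cohort size before writing.
#'
#' @param table A `"success_table"` from [build_success_tables()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_success_tables <- function(table, path) {
  if (!inherits(table, "success_table")) {
    stop("`table` must be a success_table", call. = FALSE)
  }
  n <- attr(table, "n_patients")
  if (!all(table$success + table$failure == n)) {
    stop("success and failure counts do not sum to the cohort size",
         call. = FALSE)
  }
  out <- data.frame(
    length = ordinal_label(table$m),
    success_count = table$success,
    success_pct = sprintf("%.1f", round_half_up(100 * table$success / n, 1L)),
    failure_count = table$failure,
    failure_pct = sprintf("%.1f", round_half_up(100 * table$failure / n, 1L))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit -> truncated prediction -> boosting ->
#' ROC evaluation on a synthetic cohort and writes every artefact to
#' `config$out_dir`: `trajectories.csv`, `covariates.csv`, `truth.json`,
#' `fits.csv`, `predictions.csv`, `success_effectiveness.csv`,
#' `success_remission.csv`, `comparisons.json`, `importance.csv`,
#' `scores.csv`, `roc.json`, `roc_curve.csv` and a human-readable
#' `report.txt`. Fully deterministic given the simulation and boosting
#' seeds, which are recorded in the report header.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `fits`, `global_r2`, `analysis`
#'   (truncated-prediction records and tables), `comparisons`, `model`,
#'   `importance`, `roc`, `auc`, `auc_ci`, `operating_point`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  say <- function(...) if (config$verbose) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("simulating cohort (n = ", config$simulation$n_patients,
      ", seed ", config$simulation$seed, ")")
  cohort <- stage("simulate", simulate_cohort(config$simulation))
  covariates <- stage("simulate", simulate_covariates(cohort))
  write_trajectories(cohort, out("trajectories.csv"))
  utils::write.csv(covariates, out("covariates.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- lapply(cohort$patients, function(p) {
    c(as.list(p$true_params), list(true_outcome = p$true_outcome))
  })
  names(truth) <- vapply(cohort$patients, function(p) p$trajectory$patient_id, "")
  jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE, digits = NA)

  say("fitting remission curves")
  trajectories <- cohort_trajectories(cohort)
  fits <- stage("fit", lapply(trajectories, fit_patient, mcsd = config$mcsd))
  global_r2 <- r_squared_global(fits)
  fits_df <- data.frame(
    patient_id = vapply(fits, `[[`, "", "patient_id"),
    K = vapply(fits, `[[`, 0, "K"),
    a = vapply(fits, `[[`, 0, "a"),
    b = vapply(fits, `[[`, 0, "b"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    converged = vapply(fits, `[[`, TRUE, "converged")
  )
  utils::write.csv(fits_df, out("fits.csv"), row.names = FALSE, quote = FALSE)

  say("truncated-course prediction (m = ",
      paste(range(config$lengths), collapse = ".."), ")")
  analysis <- stage("predict-truncated",
                    build_success_tables(trajectories, lengths = config$lengths,
                                         mcsd = config$mcsd))
  utils::write.csv(analysis$records, out("predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  write_success_tables(analysis$effectiveness, out("success_effectiveness.csv"))
  write_success_tables(analysis$remission, out("success_remission.csv"))

  comparisons <- list()
  if (all(2:9 %in% config$lengths)) {
    comparisons$effectiveness_2to4_vs_5to9 <- stage(
      "predict-truncated",
      pooled_group_comparison(analysis$effectiveness,
                              list("2-4" = 2:4, "5-9" = 5:9)))
    comparisons$remission_three_groups <- stage(
      "predict-truncated",
      pooled_group_comparison(analysis$remission,
                              list("2-4" = 2:4, "5-7" = 5:7, "8-9" = 8:9)))
    json_cmp <- lapply(comparisons, function(cmp) {
      list(contingency = apply(cmp$contingency, 1L, as.list),
           chi2 = cmp$chi2, df = cmp$df, p = cmp$p,
           pairwise = lapply(cmp$pairwise, function(pw) {
             pw[c("groups", "chi2", "df", "p")]
           }))
    })
    jsonlite::write_json(json_cmp, out("comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  say("training gradient-boosting model (M = ", config$gbm$M, ")")
  features <- covariates[, covariate_names(), drop = FALSE]
  split <- train_test_split(cbind(features, outcome = covariates$outcome,
                                  patient_id = covariates$patient_id),
                            ratio = 0.7, seed = config$gbm$seed)
  model <- stage("gbm-train",
                 gbm_fit(split$train[, covariate_names()],
                         split$train$outcome, config$gbm))
  importance <- feature_importance(model)
  utils::write.csv(importance, out("importance.csv"), row.names = FALSE,
                   quote = FALSE)
  score_df <- rbind(
    data.frame(patient_id = split$train$patient_id, set = "train",
               score = gbm_predict(model, split$train[, covariate_names()]),
               outcome = split$train$outcome),
    data.frame(patient_id = split$test$patient_id, set = "test",
               score = gbm_predict(model, split$test[, covariate_names()]),
               outcome = split$test$outcome)
  )
  utils::write.csv(score_df, out("scores.csv"), row.names = FALSE, quote = FALSE)

  say("evaluating on the held-out test set")
  test_scores <- score_df$score[score_df$set == "test"]
  test_labels <- score_df$outcome[score_df$set == "test"]
  roc <- stage("evaluate", roc_curve(test_scores, test_labels))
  a <- auc(roc)
  ci <- stage("evaluate",
              auc_confidence_interval(test_scores, test_labels))
  op <- optimal_operating_point(roc)
  jsonlite::write_json(
    list(auc = a, ci_low = ci[1L], ci_high = ci[2L],
         threshold = op$threshold, sensitivity = op$sensitivity,
         specificity = op$specificity, youden_j = op$youden_j,
         n_test = length(test_labels)),
    out("roc.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
               specificity = roc$specificity),
    out("roc_curve.csv"), row.names = FALSE, quote = FALSE)

  write_report(out("report.txt"), config, global_r2, analysis, comparisons,
               importance, a, ci, op)
  say("done; outputs in ", config$out_dir)
  invisible(list(fits = fits, global_r2 = global_r2, analysis = analysis,
                 comparisons = comparisons, model = model,
                 importance = importance, roc = roc, auc = a, auc_ci = ci,
                 operating_point = op, out_dir = config$out_dir))
}

write_report <- function(path, config, global_r2, analysis, comparisons,
                         importance, a, ci, op) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Remission-curve pipeline report")
  w("  cohort seed: %d   boosting seed: %d   n = %d   MCSD = %.1f",
    config$simulation$seed, config$gbm$seed,
    config$simulation$n_patients, config$mcsd)
  w("")
  w("Global coefficient of determination (pooled): %.4f", global_r2)
  w("")
  w("Effectiveness-prediction success by treatment length:")
  for (i in seq_len(nrow(analysis$effectiveness))) {
    r <- analysis$effectiveness[i, ]
    w("  %-8s %3d successful (%.1f%%), %3d unsuccessful",
      ordinal_label(r$m), r$success, r$success_pct, r$failure)
  }
  w("")
  w("Remission-magnitude success by treatment length:")
  for (i in seq_len(nrow(analysis$remission))) {
    r <- analysis$remission[i, ]
    w("  %-8s %3d successful (%.1f%%), %3d unsuccessful",
      ordinal_label(r$m), r$success, r$success_pct, r$failure)
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    w("")
    w("Pooled comparison [%s]: chi2 = %.3f, df = %d, p = %.4g",
      nm, cmp$chi2, cmp$df, cmp$p)
    for (pw in cmp$pairwise) {
      w("  %s: chi2 = %.3f, p = %.4g",
        paste(pw$groups, collapse = " vs "), pw$chi2, pw$p)
    }
  }
  w("")
  w("Gradient-boosting evaluation (held-out test set):")
  w("  AUC = %.3f  [95%% CI %.3f - %.3f]", a, ci[1L], ci[2L])
  w("  Youden-optimal point: sensitivity %.3f, specificity %.3f, J = %.3f",
    op$sensitivity, op$specificity, op$youden_j)
  w("")
  w("Top five features by split-gain importance:")
  top <- utils::head(importance, 5L)
  for (i in seq_len(nrow(top))) {
    w("  %d. %-30s %.4f", i, top$feature[i], top$importance[i])
  }
}
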