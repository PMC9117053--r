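# Truncated-treatment predictive-power analysis.
#
# For each treatment length m = 2..9, the remission curve is refitted on
# sessions 1..m only and extrapolated to session 10. Two success notions
# are scored against the 1.2-point minimal clinically significant
# difference (MCSD): (i) effectiveness - does the predicted course agree
# with the actual course on whether pain fell by more than 1.2 points;
# (ii) remission magnitude - is the predicted final score within 1.2
# points of the measured one. Success rates per m are tabulated and
# compared by Pearson chi-square, with cells pooled into coarser length
# groups to limit multiple comparisons.

#' Fit the remission curve on a truncated course
#'
#' Refits the logistic remission curve using only the first `m` sessions,
#' with the upper asymptote still fixed by the full rule on the
#' first-session score. With `m = 2` the two-parameter curve interpolates
#' both points and the fit is flagged `exact_fit`.
#'
#' @param traj A [vas_trajectory()].
#' @param m Treatment length to use, between 2 and the number of sessions.
#' @inheritParams fit_patient
#' @return A `"curve_fit"` on sessions 1..m.
#' @export
fit_truncated <- function(traj, m, lower = 0, mcsd = 1.2, control = list()) {
  if (!inherits(traj, "vas_trajectory")) {
    stop("`traj` must be a vas_trajectory", call. = FALSE)
  }
  m <- as.integer(m)
  if (m < 2L) stop("`m` must be at least 2", call. = FALSE)
  if (m > length(traj$sessions)) {
    stop(sprintf("`m` = %d exceeds the %d available sessions",
                 m, length(traj$sessions)), call. = FALSE)
  }
  sub <- vas_trajectory(traj$patient_id, traj$sessions[1:m], traj$vas[1:m])
  fit_patient(sub, lower = lower, mcsd = mcsd, control = control)
}

#' Predict the final-session VAS from a fitted curve
#'
#' Evaluates the fitted remission curve at the final rating time point
#' (session 10 by default) and clips to the VAS scale `[0, 10]`.
#'
#' @param fit A `"curve_fit"`.
#' @param x_final Final session index (default 10).
#' @return Predicted VAS at `x_final`, in `[0, 10]`.
#' @export
predict_final_vas <- function(fit, x_final = 10) {
  if (!inherits(fit, "curve_fit")) stop("`fit` must be a curve_fit", call. = FALSE)
  val <- logistic_curve(x_final, fit$K, fit$a, fit$b, fit$lower)
  min(10, max(0, val))
}

#' Classify clinical effectiveness from the VAS decline
#'
#' A course is clinically effective when the VAS falls by strictly more
#' than the MCSD (1.2 points) over the whole course; a decline of exactly
#' 1.2 is not effective.
#'
#' @param decline VAS decline over the course (first score minus final),
#'   vectorised.
#' @param mcsd MCSD threshold (default 1.2).
#' @return Logical vector.
#' @details The comparison carries a 1e-9 guard so that declines that are
#'   exactly the MCSD on the 0.1-point recording grid are classified as
#'   at-threshold (not effective) despite binary floating-point
#'   representation.
#' @export
classify_effectiveness <- function(decline, mcsd = 1.2) {
  decline > mcsd + 1e-9
}

#' Remission-magnitude prediction success
#'
#' The remission magnitude is successfully predicted when the predicted
#' final VAS lies within the MCSD (1.2 points, inclusive) of the measured
#' final VAS.
#'
#' @param predicted_final,actual_final Final-session VAS values,
#'   vectorised.
#' @param mcsd MCSD threshold (default 1.2).
#' @return Logical vector.
#' @details As in [classify_effectiveness()], a 1e-9 guard keeps
#'   differences that equal the MCSD on the 0.1-point recording grid on
#'   the inclusive (success) side of the boundary.
#' @export
remission_success <- function(predicted_final, actual_final, mcsd = 1.2) {
  abs(predicted_final - actual_final) <= mcsd + 1e-9
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Build per-length prediction records and success tables
#'
#' For every patient with a complete course and every treatment length `m`
#' in `lengths`, fits the truncated curve, extrapolates the final VAS, and
#' scores both the effectiveness agreement and the remission-magnitude
#' closeness against the MCSD rule. Declines (predicted and actual) are
#' anchored at the measured first-session score. Patients without the full
#' set of sessions are excluded with a warning; non-converged truncated
#' fits still contribute their best-iterate prediction so every table row
#' sums to the cohort size.
#'
#' @param trajectories List of [vas_trajectory()] objects or a
#'   `"synthetic_cohort"`.
#' @param lengths Treatment lengths to evaluate (default `2:9`).
#' @param mcsd MCSD threshold, VAS points (default 1.2).
#' @param n_sessions Required full course length (default 10).
#' @inheritParams fit_patient
#' @return List of class `"prediction_analysis"`:
#'   \describe{
#'     \item{records}{data.frame, one row per patient x m: `patient_id`,
#'       `m`, `predicted_final`, `actual_final`, `predicted_decline`,
#'       `actual_decline`, `effective_pred`, `effective_actual`,
#'       `effectiveness_success`, `remission_success`, `converged`.}
#'     \item{effectiveness, remission}{`"success_table"` data.frames with
#'       columns `m`, `success`, `failure`, `success_pct` (one decimal,
#'       half-up) and attribute `n_patients`.}
#'   }
#' @export
build_success_tables <- function(trajectories, lengths = 2:9, mcsd = 1.2,
                                 n_sessions = 10L, lower = 0,
                                 control = list()) {
  if (inherits(trajectories, "synthetic_cohort")) {
    trajectories <- cohort_trajectories(trajectories)
  }
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 2L) || any(lengths >= n_sessions)) {
    stop("`lengths` must lie in 2..(n_sessions - 1)", call. = FALSE)
  }
  complete <- vapply(trajectories, function(t) length(t$sessions) == n_sessions,
                     logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " patient(s) without a complete ", n_sessions,
            "-session course excluded", call. = FALSE)
    trajectories <- trajectories[complete]
  }
  if (length(trajectories) == 0L) stop("no complete trajectories", call. = FALSE)

  rows <- vector("list", length(trajectories) * length(lengths))
  k <- 0L
  for (traj in trajectories) {
    first <- traj$vas[1L]
    actual_final <- traj$vas[n_sessions]
    actual_decline <- first - actual_final
    for (m in lengths) {
      fit <- fit_truncated(traj, m, lower = lower, mcsd = mcsd,
                           control = control)
      pred_final <- predict_final_vas(fit, x_final = traj$sessions[n_sessions])
      pred_decline <- first - pred_final
      eff_pred <- classify_effectiveness(pred_decline, mcsd)
      eff_act <- classify_effectiveness(actual_decline, mcsd)
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = traj$patient_id, m = m,
        predicted_final = pred_final, actual_final = actual_final,
        predicted_decline = pred_decline, actual_decline = actual_decline,
        effective_pred = eff_pred, effective_actual = eff_act,
        effectiveness_success = eff_pred == eff_act,
        remission_success = remission_success(pred_final, actual_final, mcsd),
        converged = fit$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows)
  structure(
    list(records = records,
         effectiveness = success_table(records, "effectiveness_success"),
         remission = success_table(records, "remission_success")),
    class = "prediction_analysis"
  )
}

success_table <- function(records, column) {
  n <- length(unique(records$patient_id))
  succ <- tapply(records[[column]], records$m, sum)
  ms <- as.integer(names(succ))
  tab <- data.frame(
    m = ms,
    success = as.integer(succ),
    failure = n - as.integer(succ),
    success_pct = round_half_up(100 * as.integer(succ) / n, 1L)
  )
  stopifnot(all(tab$success + tab$failure == n))
  structure(tab, n_patients = n,
            class = c("success_table", "data.frame"))
}

#' @export
print.prediction_analysis <- function(x, ...) {
  n <- attr(x$effectiveness, "n_patients")
  cat("Truncated-course prediction analysis,", n, "patients\n")
  cat("\nEffectiveness prediction (MCSD agreement):\n")
  print.data.frame(x$effectiveness, row.names = FALSE)
  cat("\nRemission-magnitude prediction (|predicted - actual| <= MCSD):\n")
  print.data.frame(x$remission, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test on a success/failure contingency table
#'
#' Pearson statistic without continuity correction; degrees of freedom
#' `(rows - 1) * (cols - 1)`.
#'
#' @param contingency Integer matrix, one row per group, columns
#'   (success, failure); at least 2 rows.
#' @return List with `chi2`, `df`, `p` and the `expected` counts.
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (nrow(contingency) < 2L || ncol(contingency) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(contingency < 0) || anyNA(contingency)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("degenerate table: a zero marginal leaves expected counts at 0",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = ht$expected)
}

#' Pooled-cell group comparison of success rates
#'
#' Pools the per-length success/failure counts into the given treatment-
#' length groups (e.g. lengths 2--4 vs 5--9) and runs the Pearson
#' chi-square on the pooled table. With three or more groups, pairwise
#' 2x2 comparisons of consecutive groups are also returned, mirroring the
#' follow-up contrasts used after an overall significant result.
#'
#' @param table A `"success_table"`.
#' @param grouping Named list of integer vectors partitioning the table's
#'   `m` values, e.g. `list("2-4" = 2:4, "5-9" = 5:9)`; at least 2 groups.
#' @return List of class `"pooled_comparison"`: `grouping`, `contingency`
#'   (group x success/failure), `chi2`, `df`, `p`, and `pairwise` (list of
#'   consecutive-pair tests, present when there are 3+ groups).
#' @export
pooled_group_comparison <- function(table, grouping) {
  if (!inherits(table, "success_table")) {
    stop("`table` must be a success_table", call. = FALSE)
  }
  if (!is.list(grouping) || length(grouping) < 2L) {
    stop("`grouping` must be a list of at least 2 groups", call. = FALSE)
  }
  pooled_m <- sort(unlist(grouping))
  if (anyDuplicated(pooled_m) || !setequal(pooled_m, table$m)) {
    stop("`grouping` must partition the table's treatment lengths",
         call. = FALSE)
  }
  if (is.null(names(grouping))) {
    names(grouping) <- vapply(grouping, function(g) {
      paste(range(g), collapse = "-")
    }, "")
  }
  cont <- t(vapply(grouping, function(g) {
    idx <- table$m %in% g
    c(success = sum(table$success[idx]), failure = sum(table$failure[idx]))
  }, c(success = 0, failure = 0)))
  test <- chi_square_test(cont)
  pairwise <- NULL
  if (nrow(cont) >= 3L) {
    pairwise <- lapply(seq_len(nrow(cont) - 1L), function(i) {
      sub <- cont[c(i, i + 1L), , drop = FALSE]
      c(list(groups = rownames(sub)), chi_square_test(sub)[c("chi2", "df", "p")])
    })
    names(pairwise) <- vapply(pairwise, function(p) {
      paste(p$groups, collapse = " vs ")
    }, "")
  }
  structure(
    list(grouping = grouping, contingency = cont,
         chi2 = test$chi2, df = test$df, p = test$p, pairwise = pairwise),
    class = "pooled_comparison"
  )
}

#' @export
print.pooled_comparison <- function(x, ...) {
  cat("Pooled success-rate comparison\n")
  print(x$contingency)
  cat(sprintf("chi2 = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  if (!is.null(x$pairwise)) {
    for (pw in x$pairwise) {
      cat(sprintf("  %s: chi2 = %.3f, p = %.4g\n",
                  paste(pw$groups, collapse = " vs "), pw$chi2, pw$p))
    }
  }
  invisible(x)
}
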