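# ROC evaluation of classifier scores: curve, trapezoidal AUC, DeLong or
# bootstrap confidence interval, and the Youden-optimal operating point.

#' ROC curve of classifier scores
#'
#' Enumerates one operating point per unique score threshold (a sample is
#' called positive when its score is at or above the threshold), plus the
#' all-negative endpoint at threshold `Inf`. Sensitivity is TP/(TP+FN)
#' and specificity TN/(TN+FP); higher scores mean the positive class.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return Object of class `"roc_result"`: list with `thresholds`
#'   (decreasing, starting at `Inf`), `sensitivity`, `specificity`,
#'   `n_pos`, `n_neg`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("`labels` must be binary 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to form an ROC curve", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- numeric(length(thr))
  spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos_call <- scores >= thr[i]
    sens[i] <- sum(pos_call & labels == 1) / n_pos
    spec[i] <- sum(!pos_call & labels == 0) / n_neg
  }
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         n_pos = n_pos, n_neg = n_neg, scores = scores, labels = labels),
    class = "roc_result"
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the (1 - specificity, sensitivity) curve. For
#' threshold-enumerated curves this equals the Mann-Whitney concordance
#' probability (ties counted one half): the probability that a random
#' positive scores above a random negative.
#'
#' @param roc A `"roc_result"` from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  if (!inherits(roc, "roc_result")) stop("`roc` must be a roc_result", call. = FALSE)
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Confidence interval for the AUC
#'
#' DeLong variance-based interval by default (delegated to
#' \pkg{pROC}), or a seeded stratified percentile bootstrap. The interval
#' is clipped to `[0, 1]`; a zero confidence level degenerates to the
#' point estimate.
#'
#' @param scores,labels As in [roc_curve()].
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed (default 1).
#' @return Numeric `c(low, high)` with `low <= auc <= high`.
#' @export
auc_confidence_interval <- function(scores, labels, level = 0.95,
                                    method = c("delong", "bootstrap"),
                                    n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  roc <- roc_curve(scores, labels)
  a <- auc(roc)
  if (level <= 0) return(c(a, a))
  if (min(roc$n_pos, roc$n_neg) < 5L) {
    warning("fewer than 5 samples in a class; interval may be unstable",
            call. = FALSE)
  }
  if (method == "delong") {
    pr <- pROC::roc(response = roc$labels, predictor = roc$scores,
                    levels = c(0, 1), direction = "<", quiet = TRUE)
    ci <- pROC::ci.auc(pr, conf.level = level, method = "delong")
    out <- c(ci[1L], ci[3L])
  } else {
    set.seed(seed)
    pos <- which(roc$labels == 1)
    neg <- which(roc$labels == 0)
    stats_boot <- vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      auc(roc_curve(roc$scores[idx], roc$labels[idx]))
    }, numeric(1))
    out <- unname(stats::quantile(stats_boot,
                                  c((1 - level) / 2, 1 - (1 - level) / 2)))
    out <- c(min(out[1L], a), max(out[2L], a))
  }
  pmin(1, pmax(0, out))
}

#' Youden index
#'
#' `J = sensitivity + specificity - 1`, summarising one ROC operating
#' point.
#'
#' @param sensitivity,specificity Values in `[0, 1]`, vectorised.
#' @return Youden's J.
#' @examples
#' youden_index(0.933, 0.875) # 0.808
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  sensitivity + specificity - 1
}

#' Youden-optimal operating point
#'
#' Selects the threshold maximising Youden's J; ties resolve to the lower
#' threshold (the more sensitive operating point).
#'
#' @param roc A `"roc_result"`.
#' @return List with `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
optimal_operating_point <- function(roc) {
  if (!inherits(roc, "roc_result")) stop("`roc` must be a roc_result", call. = FALSE)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(roc$thresholds[best])]
  list(threshold = roc$thresholds[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick],
       youden_j = j[pick])
}

#' @export
print.roc_result <- function(x, ...) {
  a <- auc(x)
  op <- optimal_operating_point(x)
  cat(sprintf(
    "ROC: %d positives / %d negatives, AUC = %.4f\n  Youden-optimal point: threshold %.4g, sensitivity %.3f, specificity %.3f, J = %.3f\n",
    x$n_pos, x$n_neg, a, op$threshold, op$sensitivity, op$specificity,
    op$youden_j))
  invisible(x)
}
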