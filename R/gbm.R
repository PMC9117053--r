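# Least-squares gradient boosting with regression-tree base learners.
#
# Forward-stagewise boosting exactly as the study algorithm prescribes:
# the initial model is F0(x) = 0 and the initial residuals are the 0/1
# outcomes themselves; at each of M iterations a depth-limited CART
# regression tree is fitted to the current residuals, the model is updated
# F_m = F_{m-1} + mu * tree, and the residuals are shrunk accordingly; the
# final model is the shrunken sum of all trees. The binary efficacy label
# is boosted literally under squared-error loss (scores clipped to [0,1]
# act as class probabilities); a logistic-deviance mode is available for
# comparison.

#' Gradient-boosting configuration
#'
#' Defaults are the tuned hyperparameter tuple of the study model:
#' 1000 trees, learning rate 0.1, tree depth 4, minimum 2 samples to
#' split and 1 per leaf, no row subsampling, square-root feature
#' subsampling at each split, seed 10. `max_leaves` is the terminal-node
#' bound L implied by the depth (`2^max_depth`); the interaction depth in
#' the d = L - 1 sense is then L - 1.
#'
#' @param M Number of boosting iterations/trees (default 1000).
#' @param mu Shrinkage (learning rate) in `[0, 1]` (default 0.1).
#' @param max_depth Maximum tree depth (default 4; depth 0 is a stump-free
#'   single leaf).
#' @param max_leaves Maximum terminal nodes L (default `2^max_depth`).
#' @param min_samples_split Minimum node size to consider splitting
#'   (default 2).
#' @param min_samples_leaf Minimum samples per child (default 1).
#' @param subsample Row-subsampling fraction per iteration (default 1 =
#'   all rows).
#' @param max_features `"sqrt"` to consider a random square-root-sized
#'   feature subset at each split, `"all"` to consider every feature.
#' @param loss `"ls"` for literal squared-error boosting of the 0/1 label
#'   (default), `"logistic"` for deviance boosting with Newton leaf values.
#' @param seed RNG seed driving feature/row subsampling (default 10).
#' @return Object of class `"gbm_config"`.
#' @export
gbm_config <- function(M = 1000L, mu = 0.1, max_depth = 4L,
                       max_leaves = 2L^max_depth,
                       min_samples_split = 2L, min_samples_leaf = 1L,
                       subsample = 1, max_features = c("sqrt", "all"),
                       loss = c("ls", "logistic"), seed = 10L) {
  max_features <- match.arg(max_features)
  loss <- match.arg(loss)
  if (M < 1L) stop("`M` must be >= 1", call. = FALSE)
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]", call. = FALSE)
  if (max_depth < 0L) stop("`max_depth` must be >= 0", call. = FALSE)
  if (subsample <= 0 || subsample > 1) stop("`subsample` must be in (0, 1]", call. = FALSE)
  structure(
    list(M = as.integer(M), mu = mu, max_depth = as.integer(max_depth),
         max_leaves = as.integer(max_leaves),
         min_samples_split = as.integer(min_samples_split),
         min_samples_leaf = as.integer(min_samples_leaf),
         subsample = subsample, max_features = max_features,
         loss = loss, seed = as.integer(seed)),
    class = "gbm_config"
  )
}

# Greedy best split of one node. Candidate thresholds are midpoints
# between consecutive distinct sorted values of each considered feature;
# the gain is the SSE reduction sum_L^2/n_L + sum_R^2/n_R - sum^2/n.
# Ties are broken by lower feature index (features scanned in ascending
# index order) then lower threshold (first maximal gain while scanning
# thresholds in ascending order).
best_split <- function(X, r, features, min_leaf) {
  n <- length(r)
  best <- NULL
  best_gain <- 0
  for (f in features) {
    xf <- X[, f]
    o <- order(xf)
    xs <- xf[o]
    rs <- r[o]
    cs <- cumsum(rs)
    tot <- cs[n]
    i <- seq_len(n - 1L)
    valid <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & (n - i >= min_leaf)
    if (!any(valid)) next
    gain <- cs[i]^2 / i + (tot - cs[i])^2 / (n - i) - tot^2 / n
    gain[!valid] <- -Inf
    j <- which.max(gain)
    if (gain[j] > best_gain + 1e-12 * max(1, abs(best_gain))) {
      best_gain <- gain[j]
      best <- list(feature = f,
                   threshold = (xs[j] + xs[j + 1L]) / 2,
                   gain = gain[j])
    }
  }
  best
}

#' Fit a CART regression tree to residual targets
#'
#' Grows a binary regression tree by greedy SSE-reduction splits, the base
#' learner of the boosting machine. Growth stops at `max_depth`, at the
#' terminal-node bound `max_leaves`, when a node is smaller than
#' `min_samples_split`, or when no split reduces the SSE. Each leaf
#' predicts the mean residual of its training samples. When
#' `max_features = "sqrt"`, each split considers only a random
#' `ceiling(sqrt(p))`-sized feature subset drawn from the current RNG
#' stream.
#'
#' @param X Numeric feature matrix.
#' @param r Numeric target vector (residuals), length `nrow(X)`.
#' @param config A [gbm_config()]; tree-shape fields are honoured, the
#'   boosting fields ignored.
#' @return Object of class `"regression_tree"`: a data.frame of nodes
#'   (`id`, `is_leaf`, `feature`, `threshold`, `value`, `left`, `right`,
#'   `n`, `gain`), rooted at id 1.
#' @export
fit_regression_tree <- function(X, r, config = gbm_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || length(r) == 0L) stop("empty training data", call. = FALSE)
  if (nrow(X) != length(r)) stop("rows of `X` must match length of `r`", call. = FALSE)
  p <- ncol(X)
  k <- if (config$max_features == "sqrt") max(1L, ceiling(sqrt(p))) else p

  nodes <- new.env(parent = emptyenv())
  nodes$df <- list()
  nodes$n_leaves <- 1L  # the root counts as a leaf until split

  grow <- function(idx, depth) {
    id <- length(nodes$df) + 1L
    nodes$df[id] <- list(NULL)  # reserve slot so child ids do not collide
    ri <- r[idx]
    node <- list(id = id, is_leaf = TRUE, feature = NA_integer_,
                 threshold = NA_real_, value = mean(ri),
                 left = NA_integer_, right = NA_integer_,
                 n = length(idx), gain = NA_real_)
    can_split <- depth < config$max_depth &&
      length(idx) >= config$min_samples_split &&
      nodes$n_leaves < config$max_leaves
    if (can_split) {
      feats <- if (k < p) sort(sample.int(p, k)) else seq_len(p)
      sp <- best_split(X[idx, , drop = FALSE], ri, feats,
                       config$min_samples_leaf)
      if (!is.null(sp)) {
        nodes$n_leaves <- nodes$n_leaves + 1L
        go_left <- X[idx, sp$feature] <= sp$threshold
        node$is_leaf <- FALSE
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$gain <- sp$gain
        nodes$df[[id]] <- node  # reserve before recursing so ids are stable
        node$left <- grow(idx[go_left], depth + 1L)
        node$right <- grow(idx[!go_left], depth + 1L)
      }
    }
    nodes$df[[id]] <- node
    id
  }
  grow(seq_len(nrow(X)), 0L)
  nd <- nodes$df
  tree <- data.frame(
    id = vapply(nd, `[[`, integer(1), "id"),
    is_leaf = vapply(nd, `[[`, logical(1), "is_leaf"),
    feature = vapply(nd, `[[`, integer(1), "feature"),
    threshold = vapply(nd, `[[`, numeric(1), "threshold"),
    value = vapply(nd, `[[`, numeric(1), "value"),
    left = vapply(nd, `[[`, integer(1), "left"),
    right = vapply(nd, `[[`, integer(1), "right"),
    n = vapply(nd, `[[`, integer(1), "n"),
    gain = vapply(nd, `[[`, numeric(1), "gain")
  )
  class(tree) <- c("regression_tree", "data.frame")
  tree
}

#' Predict with a single regression tree
#'
#' @param tree A `"regression_tree"`.
#' @param X Numeric feature matrix.
#' @return Numeric vector of leaf values, one per row of `X`.
#' @export
predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  is_leaf <- tree$is_leaf; feat <- tree$feature; thr <- tree$threshold
  val <- tree$value; lft <- tree$left; rgt <- tree$right
  route <- function(idx, id) {
    if (is_leaf[id]) {
      out[idx] <<- val[id]
      return(invisible())
    }
    go_left <- X[idx, feat[id]] <= thr[id]
    if (any(go_left)) route(idx[go_left], lft[id])
    if (any(!go_left)) route(idx[!go_left], rgt[id])
  }
  if (nrow(X) > 0L) route(seq_len(nrow(X)), 1L)
  out
}

#' Fit the gradient-boosting machine
#'
#' Forward-stagewise least-squares boosting of a binary outcome: start at
#' `F0 = 0` with residuals equal to the outcomes, then for m = 1..M fit a
#' regression tree to the residuals, add it with shrinkage mu, and update
#' the residuals to `y - F_m(X)`. Under `loss = "logistic"` the residuals
#' are the deviance gradient `y - plogis(F)` and leaf values are Newton
#' steps.
#'
#' @param X Feature matrix or data.frame (numeric columns).
#' @param y Binary outcome vector coded 0/1.
#' @param config A [gbm_config()].
#' @return Object of class `"gbm_model"`: list with `F0` (0), `trees`
#'   (list of `"regression_tree"`), `mu`, `config`, `feature_names`,
#'   `train_loss` (per-iteration training SSE, or deviance under logistic
#'   loss), `residuals` (final), `n_features`.
#' @export
gbm_fit <- function(X, y, config = gbm_config()) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric", call. = FALSE)
  if (nrow(X) == 0L) stop("empty training data", call. = FALSE)
  if (nrow(X) != length(y)) stop("`X` rows must match length of `y`", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be coded 0/1", call. = FALSE)
  y <- as.numeric(y)
  n <- nrow(X)

  set.seed(config$seed)
  F_cur <- rep(0, n)
  r <- y - F_cur            # ls: r = y at the start
  trees <- vector("list", config$M)
  loss_path <- numeric(config$M)
  logistic <- config$loss == "logistic"

  for (m in seq_len(config$M)) {
    rows <- if (config$subsample < 1) {
      sort(sample.int(n, max(1L, floor(config$subsample * n))))
    } else seq_len(n)
    if (logistic) r <- y - stats::plogis(F_cur)
    tree <- fit_regression_tree(X[rows, , drop = FALSE], r[rows], config)
    if (logistic) {
      tree <- newton_leaf_values(tree, X[rows, , drop = FALSE],
                                 r[rows], stats::plogis(F_cur)[rows])
    }
    pred <- predict_tree(tree, X)
    F_cur <- F_cur + config$mu * pred
    r <- r - config$mu * pred
    trees[[m]] <- tree
    loss_path[m] <- if (logistic) {
      -2 * sum(y * stats::plogis(F_cur, log.p = TRUE) +
                 (1 - y) * stats::plogis(-F_cur, log.p = TRUE))
    } else {
      sum((y - F_cur)^2)
    }
  }
  structure(
    list(F0 = 0, trees = trees, mu = config$mu, config = config,
         feature_names = colnames(X), train_loss = loss_path,
         residuals = r, n_features = ncol(X)),
    class = "gbm_model"
  )
}

# replace leaf means by one Newton step sum(grad)/sum(hess) for deviance
# boosting; hess = p(1-p) per sample
newton_leaf_values <- function(tree, X, grad, p) {
  leaf_of <- leaf_assignment(tree, X)
  for (id in tree$id[tree$is_leaf]) {
    idx <- which(leaf_of == id)
    h <- sum(p[idx] * (1 - p[idx]))
    tree$value[tree$id == id] <- if (h > 1e-12) sum(grad[idx]) / h else 0
  }
  tree
}

leaf_assignment <- function(tree, X) {
  X <- as.matrix(X)
  out <- integer(nrow(X))
  route <- function(idx, id) {
    if (tree$is_leaf[id]) {
      out[idx] <<- id
      return(invisible())
    }
    go_left <- X[idx, tree$feature[id]] <= tree$threshold[id]
    if (any(go_left)) route(idx[go_left], tree$left[id])
    if (any(!go_left)) route(idx[!go_left], tree$right[id])
  }
  if (nrow(X) > 0L) route(seq_len(nrow(X)), 1L)
  out
}

#' Predict from a fitted boosting model
#'
#' The raw score is the shrunken sum of all tree predictions,
#' `F_M(x) = sum_m mu * f_m(x)`. As a class probability the score is
#' clipped to `[0, 1]` under squared-error boosting, or passed through the
#' logistic function under deviance boosting.
#'
#' @param model A `"gbm_model"`.
#' @param X Feature matrix with the same columns as at training.
#' @param type `"score"` (default) for the raw additive score, `"prob"`
#'   for the probability of the positive class.
#' @return Numeric vector, one value per row.
#' @export
gbm_predict <- function(model, X, type = c("score", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop(sprintf("model was trained on %d features, got %d",
                 model$n_features, ncol(X)), call. = FALSE)
  }
  score <- rep(model$F0, nrow(X))
  for (tree in model$trees) {
    score <- score + model$mu * predict_tree(tree, X)
  }
  if (type == "score") return(score)
  if (model$config$loss == "logistic") stats::plogis(score)
  else pmin(1, pmax(0, score))
}

#' Split-gain feature importance
#'
#' Importance of a feature is the total SSE reduction attributed to its
#' splits over all trees, normalised to sum to one. Ties rank by feature
#' index.
#'
#' @param model A `"gbm_model"`.
#' @return data.frame with columns `feature`, `importance`, sorted by
#'   decreasing importance.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "gbm_model")) stop("`model` must be a gbm_model", call. = FALSE)
  imp <- numeric(model$n_features)
  for (tree in model$trees) {
    splits <- tree[!tree$is_leaf, ]
    if (nrow(splits) > 0L) {
      agg <- tapply(splits$gain, splits$feature, sum)
      imp[as.integer(names(agg))] <- imp[as.integer(names(agg))] + agg
    }
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  nm <- model$feature_names
  if (is.null(nm)) nm <- paste0("x", seq_len(model$n_features))
  out <- data.frame(feature = nm, importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance, seq_len(nrow(out))), , drop = FALSE]
}

#' @export
print.gbm_model <- function(x, ...) {
  cat(sprintf(
    "Gradient-boosting model: %d trees, mu = %g, depth <= %d, loss = %s\n",
    length(x$trees), x$mu, x$config$max_depth, x$config$loss))
  cat(sprintf("  final training loss: %.5g\n", utils::tail(x$train_loss, 1)))
  invisible(x)
}

#' Seeded train/test split
#'
#' Permutes the rows with a seeded uniform shuffle; the first
#' `ceiling(ratio * n)` permuted rows form the training set, the rest the
#' test set. The two sets are disjoint and exhaustive.
#'
#' @param data data.frame to split.
#' @param ratio Training fraction in (0, 1) (default 0.7, the study's 7:3
#'   split).
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
train_test_split <- function(data, ratio = 0.7, seed = 10L) {
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- ceiling(ratio * n)
  list(train = data[perm[seq_len(n_train)], , drop = FALSE],
       test = data[perm[-seq_len(n_train)], , drop = FALSE])
}
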