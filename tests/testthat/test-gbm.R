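make_xy <- function(n = 60, p = 4, seed = 5, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, noise) > 0)
  list(X = X, y = y)
}

test_that("regression tree splits match brute force on a step function", {
  X <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9), ncol = 1)
  r <- c(0, 0, 0, 0, 1, 1, 1, 1)
  tree <- fit_regression_tree(X, r, gbm_config(max_depth = 1, max_features = "all"))
  split <- tree[!tree$is_leaf, ]
  expect_equal(nrow(split), 1)
  expect_equal(split$threshold, 0.5)  # midpoint of the straddling values
  expect_equal(sort(tree$value[tree$is_leaf]), c(0, 1))  # leaf = group mean
  # brute force: every candidate split's SSE reduction
  gains <- vapply(1:7, function(i) {
    sum(r)^2 / 8 * -1 + sum(r[1:i])^2 / i + sum(r[-(1:i)])^2 / (8 - i)
  }, 0)
  expect_equal(split$gain, max(gains), tolerance = 1e-12)
})

test_that("degenerate trees: no-split and constant-target cases", {
  X <- matrix(runif(20), ncol = 2)
  r <- rnorm(10)
  stump <- fit_regression_tree(X, r, gbm_config(max_depth = 0))
  expect_equal(nrow(stump), 1)
  expect_equal(stump$value, mean(r))
  const <- fit_regression_tree(X, rep(2, 10), gbm_config(max_features = "all"))
  expect_equal(nrow(const), 1)  # no split improves the SSE
  expect_error(fit_regression_tree(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("boosting bookkeeping: F0, residual identity, decomposition, monotone loss", {
  d <- make_xy()
  cfg <- gbm_config(M = 30, mu = 0.2, max_depth = 3, max_features = "all", seed = 2)
  model <- gbm_fit(d$X, d$y, cfg)
  expect_identical(model$F0, 0)
  # Eq-style decomposition: F_M(x) = sum_m mu * f_m(x)
  by_tree <- sapply(model$trees, function(t) predict_tree(t, d$X))
  expect_equal(gbm_predict(model, d$X), rowSums(cfg$mu * by_tree),
               tolerance = 1e-12)
  # residual identity at every iteration: r_m = y - F_m(X)
  F_m <- rep(0, length(d$y))
  for (m in seq_along(model$trees)) {
    F_m <- F_m + cfg$mu * by_tree[, m]
    expect_equal(sum((d$y - F_m)^2), model$train_loss[m], tolerance = 1e-9)
  }
  expect_equal(d$y - F_m, model$residuals, tolerance = 1e-9)
  # training SSE non-increasing for mu in (0, 1]
  expect_true(all(diff(model$train_loss) <= 1e-12))
})

test_that("shrinkage limits behave: mu = 0 is inert, full deep fit interpolates", {
  d <- make_xy(n = 25, p = 2, seed = 3)
  m0 <- gbm_fit(d$X, d$y, gbm_config(M = 5, mu = 0, max_features = "all"))
  expect_equal(gbm_predict(m0, d$X), rep(0, 25))
  expect_equal(m0$residuals, d$y)
  # one unshrunken tree deep enough to isolate every sample
  m1 <- gbm_fit(d$X, d$y, gbm_config(M = 1, mu = 1, max_depth = 25,
                                     max_leaves = 64L, max_features = "all"))
  expect_equal(gbm_predict(m1, d$X), d$y, tolerance = 1e-12)
  expect_equal(m1$residuals, rep(0, 25), tolerance = 1e-12)
})

test_that("predictions match an independent boosting reference", {
  skip_if_not_installed("xgboost")
  set.seed(42)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.3) > 0)
  cfg <- gbm_config(M = 25, mu = 0.3, max_depth = 3, max_features = "all",
                    subsample = 1, seed = 1)
  mine <- gbm_predict(gbm_fit(X, y, cfg), X)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  ref <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = cfg$mu,
                  max_depth = cfg$max_depth, lambda = 0, gamma = 0,
                  min_child_weight = 0, base_score = 0, tree_method = "exact"),
    data = dtrain, nrounds = cfg$M)
  expect_lt(max(abs(mine - predict(ref, dtrain))), 1e-6)
})

test_that("scores clip to probabilities and logistic mode returns calibrated values", {
  d <- make_xy(n = 80, seed = 11)
  model <- gbm_fit(d$X, d$y, gbm_config(M = 60, max_features = "all"))
  pr <- gbm_predict(model, d$X, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  lmodel <- gbm_fit(d$X, d$y, gbm_config(M = 40, loss = "logistic",
                                         max_features = "all"))
  lp <- gbm_predict(lmodel, d$X, type = "prob")
  expect_true(all(lp > 0 & lp < 1))
  # deviance decreases over training
  expect_lt(tail(lmodel$train_loss, 1), lmodel$train_loss[1])
  expect_error(gbm_predict(model, d$X[, 1:2]), "features")
})

test_that("feature importance is a normalised split-gain ranking", {
  d <- make_xy(n = 100, p = 5, seed = 6, noise = 0.1)
  model <- gbm_fit(d$X, d$y, gbm_config(M = 40, max_features = "all", seed = 2))
  imp <- feature_importance(model)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$feature[1], "x1")  # the dominant generating feature
  # a model trained on a single informative feature concentrates there
  X1 <- d$X; X1[, 2:5] <- 0
  m1 <- gbm_fit(X1, d$y, gbm_config(M = 10, max_features = "all"))
  i1 <- feature_importance(m1)
  expect_equal(i1$importance[i1$feature == "x1"], 1, tolerance = 1e-12)
})

test_that("the dominant covariate tops the importance ranking in the cohort", {
  cfg <- simulation_config(n_patients = 400, seed = 23)
  cov <- simulate_covariates(400, cfg)
  model <- gbm_fit(cov[, remcurve:::covariate_names()], cov$outcome,
                   gbm_config(M = 150, seed = 10))
  imp <- feature_importance(model)
  expect_equal(imp$feature[1], "sagittal_diameter_protrusion")
})

test_that("the 7:3 split is seeded, disjoint and exhaustive", {
  df <- data.frame(id = 1:10, z = rnorm(10))
  sp <- train_test_split(df, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_setequal(c(sp$train$id, sp$test$id), df$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- train_test_split(df, 0.7, seed = 4)
  expect_identical(sp, sp2)
  expect_error(train_test_split(df[1, , drop = FALSE]), "at least 2")
  expect_error(train_test_split(df, 1.2), "in \\(0, 1\\)")
})
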