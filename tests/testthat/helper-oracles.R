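# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# dense grid search.

# dense (a, b) grid search for the minimal logistic SSE with K fixed
grid_search_sse <- function(x, y, K, lower = 0,
                            a_grid = seq(-20, 20, by = 0.05),
                            b_grid = seq(0, 5, by = 0.02)) {
  best <- Inf
  H <- K - lower
  for (b in b_grid) {
    # vectorise over a: curve matrix length(a_grid) x length(x)
    eta <- outer(a_grid, b * x, `+`)
    fit <- lower + H * plogis(-eta)
    sse <- rowSums(sweep(fit, 2L, y)^2)
    best <- min(best, min(sse))
  }
  best
}

# Mann-Whitney concordance probability, ties counted one half
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# Pearson chi-square statistic computed from the definition
pearson_chi2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# small deterministic noise-free trajectory from known parameters; the
# baseline is chosen so the asymptote rule reproduces K exactly
consistent_trajectory <- function(K, t_star, id = "p1", sessions = 1:10) {
  b <- qlogis((K - 1.2) / K) / (t_star - 1)
  a <- -b * t_star
  y <- K * plogis(-(a + b * sessions))
  list(traj = remcurve::vas_trajectory(id, sessions, y),
       K = K, a = a, b = b)
}
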