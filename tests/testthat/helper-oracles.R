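# Independent oracles: deliberately naive implementations used only to check
# the package's answers, never sharing code with them.

# Exhaustive sign-flip enumeration of the Wilcoxon signed-rank null: every
# one of the 2^m assignments of signs to the nonzero differences is
# enumerated and the two-sided p-value read off the resulting distribution
# of the positive-rank sum.
wilcoxon_enumeration_oracle <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  m <- length(d)
  stopifnot(m <= 16)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  V_all <- as.matrix(subsets) %*% r
  p_le <- mean(V_all <= V_obs + 1e-9)
  p_ge <- mean(V_all >= V_obs - 1e-9)
  list(statistic = V_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Dense 2-parameter grid search for the 1-disease / 1-symptom noisy-OR MLE.
noisy_or_grid_oracle <- function(matrix, grid_size = 200) {
  y <- matrix$cells[, disease_ids(matrix)]
  x <- matrix$cells[, symptom_ids(matrix)]
  vals <- seq(1e-4, 1 - 1e-4, length.out = grid_size)
  best <- -Inf
  for (f in vals) {
    p1 <- 1 - (1 - vals)            # leak when disease off: p = l
    p_on <- 1 - (1 - vals) * f      # disease on
    n1_on <- sum(x == 1 & y == 1); n0_on <- sum(x == 0 & y == 1)
    n1_off <- sum(x == 1 & y == 0); n0_off <- sum(x == 0 & y == 0)
    ll <- n1_on * log(p_on) + n0_on * log(1 - p_on) +
          n1_off * log(p1) + n0_off * log(1 - p1)
    best <- max(best, max(ll))
  }
  best
}

# Brute-force noisy-OR log-likelihood, one cell at a time, built on the
# scalar conditional rather than the vectorized likelihood code.
noisy_or_ll_bruteforce <- function(model, matrix) {
  sids <- symptom_ids(matrix); dids <- disease_ids(matrix)
  total <- 0
  eps <- 1e-6
  for (p in rownames(matrix$cells)) {
    y <- matrix$cells[p, dids]
    for (s in sids) {
      pr <- noisy_or_symptom_prob(y, model$failure[s, dids], model$leak[[s]])
      pr <- min(max(pr, eps), 1 - eps)
      x <- matrix$cells[p, s]
      total <- total + x * log(pr) + (1 - x) * log(1 - pr)
    }
  }
  total
}

# Proximal-gradient (ISTA) solver for L1-penalized logistic regression,
# minimizing mean log-loss + lambda * ||beta||_1 with an unpenalized
# intercept; slow but independent of glmnet.
l1_logistic_oracle <- function(X, y, lambda, iters = 20000, step = 0.25) {
  n <- nrow(X)
  beta <- rep(0, ncol(X)); b0 <- 0
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (i in seq_len(iters)) {
    eta <- drop(X %*% beta) + b0
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, mu - y)) / n
    beta <- soft(beta - step * g, step * lambda)
    b0 <- b0 - step * mean(mu - y)
  }
  list(beta = beta, intercept = b0)
}

# Rank-based AUC of true edges versus non-edges under a score matrix.
edge_auc <- function(scores, truth) {
  sc <- as.vector(scores); lab <- as.vector(truth)
  r <- rank(sc)
  (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
}
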