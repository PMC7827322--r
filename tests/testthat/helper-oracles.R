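# Independent oracles used across tests.

# Hand-rolled Newton (IRLS) logistic MLE, independent of stats::glm and of
# the package's optimizer. X includes no intercept column; one is added.
newton_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  X1 <- cbind(1, as.matrix(X))
  beta <- numeric(ncol(X1))
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- drop(crossprod(X1, y - p))
    info <- crossprod(X1 * W, X1)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X1 %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X1 * (p * (1 - p)), X1)
  list(coef = beta, se = sqrt(diag(solve(info))),
       loglik = sum(y * eta - log(1 + exp(eta))))
}

# Rank-cut quartile oracle: sort the column, cut at empirical quartile
# boundaries of the sorted positions.
rank_cut_oracle <- function(x, q) {
  r <- rank(x, ties.method = "average")
  cuts <- quantile(r, probs = seq_len(q - 1) / q, names = FALSE)
  vapply(r, function(ri) sum(ri > cuts), numeric(1))
}

# Small logistic dataset generator for oracle-equivalence checks.
random_logistic_data <- function(n, k, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * k), n, k)
    y <- rbinom(n, 1, plogis(drop(X %*% runif(k, -1, 1))))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    list(X = X, y = y)
  })
}
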