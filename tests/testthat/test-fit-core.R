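make_small_problem <- function(seed = 3, n = 60) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                              dimnames = list(NULL, paste0("x", 1:4))))
    sc <- score_quantiles(X, q = 4)
    y <- rbinom(n, 1, plogis(0.7 * sc$x1 - 1))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    list(scores = sc, y = y,
         groups = group_structure(list(g1 = c("x1", "x2"),
                                       g2 = c("x3", "x4"))))
  })
}

test_that("negative log-likelihood matches hand arithmetic", {
  pr <- make_small_problem()
  J <- 2; C <- 4
  # all parameters zero: p = 1/2 everywhere
  expect_equal(
    gwqs_negloglik(c(0, 0, 0, rep(0.25, C)), pr$scores, pr$groups,
                   y = pr$y),
    length(pr$y) * log(2))

  # two subjects, one group, one component, w = 1, q = (0, 1), y = (0, 1),
  # beta0 = 0, beta1 = 1: -log(1/2) - log(e/(1+e))
  sc1 <- structure(data.frame(x1 = c(0L, 1L)), q = 2L)
  val <- gwqs_negloglik(c(0, 1, 1), sc1, list(g = "x1"), y = c(0, 1))
  expect_equal(val, -(log(0.5) + log(exp(1) / (1 + exp(1)))))

  # logistic symmetry: flip y and negate the coefficients
  p1 <- c(0.3, -0.8, 0.5, 0.6, 0.4, 0.1, 0.9)
  p2 <- c(-0.3, 0.8, -0.5, 0.6, 0.4, 0.1, 0.9)
  expect_equal(
    gwqs_negloglik(p1, pr$scores, pr$groups, y = pr$y),
    gwqs_negloglik(p2, pr$scores, pr$groups, y = 1 - pr$y))
  expect_error(gwqs_negloglik(c(Inf, 0, 0, rep(0.25, 4)), pr$scores,
                              pr$groups, y = pr$y), "finite")
  expect_error(gwqs_negloglik(rep(0, 5), pr$scores, pr$groups, y = pr$y),
               "length")
})

test_that("analytic gradient agrees with numerical differentiation", {
  pr <- make_small_problem(seed = 8)
  pd <- gwqsr:::prep_fit_data(pr$scores, pr$groups, NULL, pr$y)
  obj <- gwqsr:::make_objective(pd)
  withr::with_seed(2, par <- rnorm(1 + 2 + 0 + 2, sd = 0.5))
  g_num <- vapply(seq_along(par), function(i) {
    h <- 1e-6; e <- numeric(length(par)); e[i] <- h
    (obj$fn(par + e) - obj$fn(par - e)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(obj$gr(par)), g_num, tolerance = 1e-5)
})

test_that("constrained fit satisfies the simplex and improves on its start", {
  pr <- make_small_problem(seed = 5, n = 120)
  fit <- fit_constrained_mle(pr$scores, pr$groups, y = pr$y)
  for (g in c("g1", "g2")) {
    sel <- pr$groups$component[pr$groups$group == g]
    expect_equal(sum(fit$weights[sel]), 1, tolerance = 1e-12)
    expect_true(all(fit$weights[sel] >= 0 & fit$weights[sel] <= 1))
  }
  ll0 <- -gwqs_negloglik(c(0, 0, 0, rep(0.5, 4)), pr$scores, pr$groups,
                         y = pr$y)
  expect_gte(fit$loglik, ll0)
  expect_true(all(is.finite(fit$test_stats)))
  expect_error(fit_constrained_mle(pr$scores, pr$groups, y = rep(1, 120)),
               "both classes")
})

test_that("a singleton group carries weight exactly 1", {
  pr <- make_small_problem(seed = 6)
  groups <- list(g1 = c("x1", "x2", "x3"), solo = "x4")
  fit <- fit_constrained_mle(pr$scores, groups, y = pr$y)
  expect_identical(unname(fit$weights["x4"]), 1)
})

test_that("the fit recovers a dominant component weight", {
  # one group of 5, single truly important component at OR 3, n = 500
  w_hat <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      R <- build_correlation_matrix(5, within = 0.5, across = 0.1)
      X <- matrix(rnorm(500 * 5), 500) %*% chol(R)
      colnames(X) <- paste0("x", 1:5)
      sc <- score_quantiles(as.data.frame(X), q = 4)
      y <- rbinom(500, 1, plogis(log(3) * (sc$x1 - 1.5)))
      fit_constrained_mle(sc, list(g = paste0("x", 1:5)), y = y)$weights[1]
    })
  }, numeric(1))
  expect_gt(mean(w_hat), 0.8)
})

test_that("bootstrap ensembles are deterministic and average correctly", {
  pr <- make_small_problem(seed = 12, n = 150)
  f1 <- bootstrap_ensemble(pr$scores, pr$groups, y = pr$y, b = 5, seed = 77)
  f2 <- bootstrap_ensemble(pr$scores, pr$groups, y = pr$y, b = 5, seed = 77)
  expect_identical(f1, f2)

  # resampling disabled reproduces the training fit itself
  f0 <- bootstrap_ensemble(pr$scores, pr$groups, y = pr$y, b = 1, seed = 1,
                           resample = FALSE)
  direct <- fit_constrained_mle(pr$scores, pr$groups, y = pr$y)
  expect_equal(f0[[1]]$weights, direct$weights)
  expect_equal(f0[[1]]$loglik, direct$loglik)

  # single-fit averaging is the identity
  w1 <- average_weights(f0, pr$groups)
  expect_equal(w1$weight, unname(direct$weights[w1$component]))
})

test_that("test-statistic averaging follows the weighted-mean formula", {
  groups <- group_structure(list(g = c("a", "b")))
  mk <- function(w, t) {
    structure(list(weights = setNames(w, c("a", "b")), beta0 = 0,
                   beta = c(g = 1), phi = numeric(0),
                   test_stats = c(g = t), se_beta = 1, loglik = 0,
                   converged = TRUE, counts = NULL),
              class = "gwqs_mle")
  }
  # symmetric statistics average symmetrically
  avg <- average_weights(list(mk(c(1, 0), 2), mk(c(0, 1), -2)), groups)
  expect_equal(avg$weight, c(0.5, 0.5))
  # (0.8 * 1 + 0.2 * 3) / 4 = 0.35
  avg2 <- average_weights(list(mk(c(0.8, 0.2), 1), mk(c(0.2, 0.8), 3)),
                          groups)
  expect_equal(avg2$weight, c(0.35, 0.65))
  # all-zero statistics fall back to the unweighted mean with a warning
  expect_warning(
    avg3 <- average_weights(list(mk(c(1, 0), 0), mk(c(0, 1), 0)), groups),
    "unweighted")
  expect_equal(avg3$weight, c(0.5, 0.5))
  # non-converged fits are excluded
  bad <- mk(c(0, 1), 100); bad$converged <- FALSE
  avg4 <- average_weights(list(mk(c(1, 0), 2), bad), groups)
  expect_equal(avg4$weight, c(1, 0))
})

test_that("index construction is the weighted quantile sum", {
  sc <- structure(data.frame(a = c(3L, 0L), b = c(1L, 0L)), q = 4L)
  groups <- group_structure(list(g = c("a", "b")))
  idx <- construct_indices(sc, groups,
                           tibble::tibble(component = c("a", "b"),
                                          weight = c(0.5, 0.5)))
  expect_equal(idx$g, c(2, 0))
  idx2 <- construct_indices(sc, groups,
                            tibble::tibble(component = c("a", "b"),
                                           weight = c(1, 0)))
  expect_equal(idx2$g, sc$a)
  expect_error(
    construct_indices(sc, groups,
                      tibble::tibble(component = "a", weight = 1)),
    "b")
})

test_that("validation GLM matches the independent Newton oracle", {
  for (s in 1:20) {
    d <- random_logistic_data(n = 40, k = 2, seed = 100 + s)
    idx <- data.frame(i1 = d$X[, 1], i2 = d$X[, 2])
    fit <- fit_validation_glm(idx, y = d$y)
    oracle <- newton_logistic(d$X, d$y)
    expect_equal(fit$coefficients$estimate, unname(oracle$coef),
                 tolerance = 1e-6)
    expect_equal(fit$coefficients$std_error, unname(oracle$se),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  }
})

test_that("validation GLM summaries obey the OR and CI identities", {
  d <- random_logistic_data(n = 200, k = 1, seed = 5)
  fit <- fit_validation_glm(data.frame(i = d$X[, 1]), y = d$y)
  co <- fit$coefficients
  expect_equal(co$odds_ratio, exp(co$estimate))
  expect_equal(co$conf_low, exp(co$estimate - 1.959964 * co$std_error),
               tolerance = 1e-6)
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))

  # independent index at large n: OR near 1, CI covers 1
  withr::with_seed(31, {
    y <- rbinom(2000, 1, 0.5)
    i <- rnorm(2000)
  })
  fit0 <- fit_validation_glm(data.frame(i = i), y = y)
  row <- fit0$coefficients[fit0$coefficients$term == "i", ]
  expect_lt(abs(row$estimate), 0.15)
  expect_true(row$conf_low < 1 && row$conf_high > 1)
})
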