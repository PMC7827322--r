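pen_sim <- function(seed = 14, n = 400, strength = 3) {
  simulate_scenario("A", strength, "W", n = n, seed = seed)
}

test_that("extreme penalties shrink every lasso coefficient to zero", {
  sim <- pen_sim()
  expect_warning(
    fit <- fit_lasso(sim$data, components = sim$spec$component_names,
                     nlambda = 2, lambda_min_ratio = 0.9999),
    "all-zero")
  expect_true(all(fit$coefficients$estimate == 0))
  expect_equal(fit$df, 0)
  # on a default path, the largest penalty zeroes everything
  fit_full <- fit_lasso(sim$data, components = sim$spec$component_names)
  expect_equal(fit_full$path$df[which.max(fit_full$path$lambda)], 0)
})

test_that("a vanishing penalty recovers the unpenalized logistic MLE", {
  sim <- pen_sim(seed = 15, n = 300)
  comps <- sim$spec$component_names
  sc <- score_quantiles(sim$data, q = 4, components = comps)
  oracle <- newton_logistic(as.matrix(sc), sim$data$y)
  fit <- fit_lasso(sim$data, components = comps, nlambda = 100,
                   lambda_min_ratio = 1e-7)
  path_min <- glmnet::glmnet(as.matrix(sc), sim$data$y,
                             family = "binomial", standardize = FALSE,
                             lambda = fit$path$lambda,
                             thresh = 1e-12)
  est <- as.numeric(coef(path_min, s = min(fit$path$lambda)))
  expect_equal(est[-1], unname(oracle$coef[-1]), tolerance = 1e-4)
})

test_that("lasso df is non-increasing in lambda along the path", {
  sim <- pen_sim(seed = 16)
  fit <- fit_lasso(sim$data, components = sim$spec$component_names)
  path <- fit$path[order(path_lambda <- fit$path$lambda, decreasing = TRUE), ]
  expect_true(all(diff(path$df) >= 0))  # df grows as lambda shrinks
  expect_equal(fit$df, sum(fit$coefficients$estimate != 0))
})

test_that("summed effects exponentiate coefficient sums", {
  fit <- structure(
    list(coefficients = tibble::tibble(component = c("a", "b"),
                                       estimate = c(0.2, -0.1)),
         intercept = 0, lambda = 0.1, df = 2, loglik = 0, aic = 4,
         method = "lasso"),
    class = "penalized_fit")
  expect_equal(summed_effect(fit)$odds_ratio, exp(0.1))

  fit$coefficients$estimate <- c(0, 0)
  expect_equal(summed_effect(fit)$odds_ratio, 1)

  # exp of sums equals product of exps across groups
  groups <- group_structure(list(g1 = "a", g2 = "b"))
  fit$coefficients$estimate <- c(0.4, -0.3)
  per_group <- summed_effect(fit, groups)
  expect_equal(prod(per_group$odds_ratio),
               summed_effect(fit)$odds_ratio)
})

test_that("the bi-level group MCP selects sparsely and degrades gracefully", {
  sim <- pen_sim(seed = 18, n = 500)
  fit <- fit_group_mcp(sim$data, sim$groups)
  expect_s3_class(fit, "penalized_fit")
  expect_equal(fit$method, "group_mcp")
  expect_true(fit$df >= 1 && fit$df <= 9)
  # the dominant signal components should survive selection
  est <- setNames(fit$coefficients$estimate, fit$coefficients$component)
  expect_true(any(est[c("x1", "x2")] != 0))
  expect_true(any(est[c("x6", "x7")] != 0))

  # a single group containing everything still fits (no cross-group term)
  fit1 <- fit_group_mcp(sim$data,
                        list(all = sim$spec$component_names))
  expect_s3_class(fit1, "penalized_fit")

  # huge penalties zero out all groups
  expect_warning(
    fit0 <- fit_group_mcp(sim$data, sim$groups, nlambda = 2,
                          lambda_min_ratio = 0.9999),
    "all-zero")
  expect_true(all(fit0$coefficients$estimate == 0))
})

test_that("power bounds follow their counting definitions", {
  sim <- pen_sim(seed = 19, n = 500, strength = 5)
  fit <- fit_group_mcp(sim$data, sim$groups)
  pb <- power_bounds(list(fit), list(sim$data), sim$groups)
  expect_true(all(pb$lower %in% c(0, 1)))
  expect_true(all(pb$upper %in% c(0, 1)))

  # all-zero fits give (0, 0)
  zero_fit <- structure(
    list(coefficients = tibble::tibble(
      component = sim$spec$component_names,
      estimate = rep(0, 9)),
      intercept = 0, lambda = 1, df = 0, loglik = 0, aic = 0,
      method = "lasso"),
    class = "penalized_fit")
  pb0 <- power_bounds(list(zero_fit), list(sim$data), sim$groups)
  expect_equal(pb0$lower, c(0, 0))
  expect_equal(pb0$upper, c(0, 0))

  # coefficients at the 1/Cj threshold saturate the upper bound
  sat_fit <- zero_fit
  sat_fit$coefficients$estimate <- rep(1, 9)
  pb1 <- power_bounds(list(sat_fit), list(sim$data), sim$groups)
  expect_equal(pb1$upper, c(1, 1))
})

test_that("cross-validated penalty selection is available and seeded", {
  sim <- pen_sim(seed = 23, n = 300)
  f1 <- fit_lasso(sim$data, components = sim$spec$component_names,
                  select = "cv", seed = 4)
  f2 <- fit_lasso(sim$data, components = sim$spec$component_names,
                  select = "cv", seed = 4)
  expect_identical(f1$lambda, f2$lambda)
})
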