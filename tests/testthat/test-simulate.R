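test_that("the scenario catalog encodes the study design", {
  a2w <- scenario_spec("A", 2, "W")
  expect_equal(unname(a2w$true_or), c(1 / 1.5, 1.5), tolerance = 1e-12)
  expect_equal(a2w$within, 0.5)
  expect_equal(a2w$across, 0.1)
  expect_equal(a2w$group_sizes, c(5L, 4L))
  expect_equal(unname(a2w$true_weights),
               c(0.5, 0.5, 0, 0, 0, 0.5, 0.5, 0, 0))

  c1s <- scenario_spec("C", 1, "S")
  expect_equal(unname(c1s$true_or), c(1, 1, 1))
  expect_equal(c1s$group_sizes, c(5L, 4L, 5L))
  expect_equal(c1s$n_important, c(3L, 2L, 3L))

  b3 <- scenario_spec("B", 3, "M")
  expect_equal(unname(b3$true_or), c(0.5, 2, 2))
  expect_equal(sum(b3$important), 3)

  cat <- scenario_catalog()
  expect_equal(nrow(cat), 45)
  expect_error(scenario_spec("D", 1, "W"))
  expect_error(scenario_spec("A", 7, "W"))
})

test_that("block correlation matrices have the exchangeable structure", {
  R <- build_correlation_matrix(c(2, 2), within = 0.5, across = 0.1)
  expect_equal(R[1, 2], 0.5)
  expect_equal(R[3, 4], 0.5)
  expect_equal(R[1, 3], 0.1)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R, t(R))

  expect_equal(build_correlation_matrix(c(2, 3), 0, 0), diag(5))

  # strong structure for the 14-chemical layout is positive definite
  Rs <- build_correlation_matrix(c(5, 4, 5), within = 0.9, across = 0.5)
  expect_gt(min(eigen(Rs, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(build_correlation_matrix(c(2, 2), within = 0.2, across = 0.5))
})

test_that("generated concentrations reproduce the target correlations", {
  spec <- scenario_spec("A", 1, "W", n = 60000)
  X <- generate_concentrations(spec, seed = 8)
  expect_identical(X, generate_concentrations(spec, seed = 8))
  emp <- cor(as.matrix(X))
  expect_lt(abs(emp[1, 2] - 0.5), 0.01)   # within group 1
  expect_lt(abs(emp[6, 7] - 0.5), 0.01)   # within group 2
  expect_lt(abs(emp[1, 6] - 0.1), 0.01)   # across groups
  expect_lt(abs(mean(as.matrix(X))), 0.01)
})

test_that("true indices follow the point-mass and equal-weight rules", {
  spec <- scenario_spec("B", 2, "W", n = 200)  # one important per group
  X <- generate_concentrations(spec, seed = 3)
  idx <- true_indices(X, spec)
  sc <- score_quantiles(X, q = 4)
  # weight 1 on the first component of each group: index = its score
  expect_equal(idx$g1, sc$x1)
  expect_equal(idx$g2, sc$x6)

  specA <- scenario_spec("A", 2, "W", n = 200)
  XA <- generate_concentrations(specA, seed = 4)
  idxA <- true_indices(XA, specA)
  scA <- score_quantiles(XA, q = 4)
  expect_equal(idxA$g1, 0.5 * scA$x1 + 0.5 * scA$x2)
  both_max <- which(scA$x1 == 3 & scA$x2 == 3)
  expect_true(all(idxA$g1[both_max] == 3))
})

test_that("outcome generation is balanced and matches its binomial mean", {
  spec <- scenario_spec("A", 1, "W", n = 400)
  X <- generate_concentrations(spec, seed = 5)
  idx <- true_indices(X, spec)
  out <- generate_outcome(spec, idx, seed = 6)
  # null model: p = 1/2 exactly
  expect_equal(unique(plogis(out$eta)), 0.5)
  expect_true(out$case_fraction >= 0.40 && out$case_fraction <= 0.60)

  spec5 <- scenario_spec("A", 5, "W", n = 400)
  X5 <- generate_concentrations(spec5, seed = 5)
  idx5 <- true_indices(X5, spec5)
  out5 <- generate_outcome(spec5, idx5, seed = 6)
  expect_true(out5$case_fraction >= 0.40 && out5$case_fraction <= 0.60)
  # mean simulated case fraction over many redraws approaches mean(p)
  p <- plogis(out5$eta)
  cf <- withr::with_seed(9, vapply(1:2000, function(i) {
    mean(rbinom(length(p), 1, p))
  }, numeric(1)))
  expect_equal(mean(cf), mean(p), tolerance = 0.005)
})

test_that("whole datasets regenerate deterministically from their seed", {
  s1 <- simulate_scenario("B", 4, "M", n = 250, seed = 17)
  s2 <- simulate_scenario("B", 4, "M", n = 250, seed = 17)
  expect_identical(s1$data, s2$data)
  expect_equal(ncol(s1$data), 15)  # 14 components + y
  s3 <- simulate_scenario("B", 4, "M", n = 250, seed = 18)
  expect_false(identical(s1$data$y, s3$data$y))
})
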