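# Simulation design for benchmarking grouped mixture methods: block-correlated
# multivariate-normal exposure concentrations with a case-balanced logistic
# outcome driven by true weighted quantile indices.

strength_ors <- function(n_groups, strength) {
  pos <- c(1.00, 1.50, 2.00, 2.50, 3.00)[strength]
  if (strength == 1L) return(rep(1.00, n_groups))
  c(1 / pos, rep(pos, n_groups - 1L))  # first group inverse, rest positive
}

correlation_levels <- function() {
  tibble::tibble(correlation = c("W", "M", "S"),
                 within = c(0.5, 0.7, 0.9),
                 across = c(0.1, 0.3, 0.5))
}

#' Specification of one simulation scenario
#'
#' Scenario families share the group layouts: `"A"` has 9 components in two
#' groups (5, 4) with 2 important per group; `"B"` has 14 components in
#' three groups (5, 4, 5) with 1 important per group; `"C"` is `"B"` with
#' (3, 2, 3) important. Strength levels 1-5 give true group odds ratios of
#' 1.00 (null) and then (1/1.5, 1.5, ...), (1/2, 2, ...), (1/2.5, 2.5, ...),
#' (1/3, 3, ...): the first group's association is negative, all others
#' positive. Important components in a group share equal true weights
#' summing to 1; unimportant components have true weight 0.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param strength Strength level 1 (null) to 5.
#' @param correlation `"W"` (0.5 within / 0.1 across group), `"M"`
#'   (0.7 / 0.3) or `"S"` (0.9 / 0.5).
#' @param n Sample size (1000 by default).
#' @param q Number of quantile bins used when forming the true indices.
#' @return A list of class `"scenario_spec"`: `scenario`, `strength`,
#'   `correlation`, `group_sizes`, `n_important`, `groups`
#'   (a [group_structure()]), `true_weights` (per component),
#'   `important` (logical per component), `true_or`, `true_beta` (per
#'   group), `within`, `across`, `n`, `q`.
#' @export
scenario_spec <- function(scenario = c("A", "B", "C"), strength = 1L,
                          correlation = c("W", "M", "S"),
                          n = 1000L, q = 4L) {
  scenario <- match.arg(as.character(scenario), c("A", "B", "C"))
  correlation <- match.arg(as.character(correlation), c("W", "M", "S"))
  if (!strength %in% 1:5) abort("`strength` must be in 1:5")
  sizes <- if (scenario == "A") c(5L, 4L) else c(5L, 4L, 5L)
  n_imp <- switch(scenario,
                  A = c(2L, 2L),
                  B = c(1L, 1L, 1L),
                  C = c(3L, 2L, 3L))
  J <- length(sizes)
  comp <- paste0("x", seq_len(sum(sizes)))
  grp <- rep(paste0("g", seq_len(J)), sizes)
  groups <- group_structure(split(comp, factor(grp, levels = unique(grp))))
  important <- unlist(lapply(seq_len(J), function(j) {
    c(rep(TRUE, n_imp[j]), rep(FALSE, sizes[j] - n_imp[j]))
  }))
  true_w <- unlist(lapply(seq_len(J), function(j) {
    c(rep(1 / n_imp[j], n_imp[j]), rep(0, sizes[j] - n_imp[j]))
  }))
  ors <- strength_ors(J, as.integer(strength))
  corr <- correlation_levels()
  corr <- corr[corr$correlation == correlation, ]
  structure(
    list(scenario = scenario, strength = as.integer(strength),
         correlation = correlation,
         group_sizes = sizes, n_important = n_imp, groups = groups,
         component_names = comp,
         true_weights = setNames(true_w, comp),
         important = setNames(important, comp),
         true_or = setNames(ors, attr(groups, "group_names")),
         true_beta = setNames(log(ors), attr(groups, "group_names")),
         within = corr$within, across = corr$across,
         n = as.integer(n), q = as.integer(q)),
    class = "scenario_spec")
}

#' Catalog of all simulation scenarios
#'
#' @param n,q Passed to [scenario_spec()].
#' @return A tibble with one row per (scenario, strength, correlation)
#'   combination (45 rows) and a `spec` list-column of
#'   [scenario_spec()] objects.
#' @export
scenario_catalog <- function(n = 1000L, q = 4L) {
  grid <- tidyr::expand_grid(scenario = c("A", "B", "C"),
                             strength = 1:5,
                             correlation = c("W", "M", "S"))
  grid$spec <- purrr::pmap(grid, scenario_spec, n = n, q = q)
  grid
}

#' Block exchangeable correlation matrix
#'
#' Unit diagonal, `within` for pairs in the same group and `across` for
#' pairs in different groups.
#'
#' @param group_sizes Integer vector of components per group.
#' @param within,across Correlation coefficients
#'   (`0 <= across <= within < 1`).
#' @return A positive-definite correlation matrix of dimension
#'   `sum(group_sizes)`.
#' @export
build_correlation_matrix <- function(group_sizes, within, across) {
  if (!(across >= 0 && across <= within && within < 1)) {
    abort("need 0 <= across <= within < 1")
  }
  C <- sum(group_sizes)
  g <- rep(seq_along(group_sizes), group_sizes)
  R <- matrix(across, C, C)
  same <- outer(g, g, `==`)
  R[same] <- within
  diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    abort(paste0("correlation matrix not positive definite (min eigenvalue ",
                 signif(ev, 3), ")"))
  }
  R
}

#' Draw multivariate-normal exposure concentrations
#'
#' Standard-normal marginals with the scenario's block correlation;
#' quantile scoring is invariant to marginal location and scale, so the
#' unit mean/variance choice cannot affect any downstream result.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed (the draw is deterministic given it).
#' @return A tibble of `spec$n` rows and one column per component.
#' @export
generate_concentrations <- function(spec, seed = 1L) {
  R <- build_correlation_matrix(spec$group_sizes, spec$within, spec$across)
  L <- chol(R)
  X <- with_local_seed(seed, matrix(rnorm(spec$n * ncol(R)), spec$n)) %*% L
  colnames(X) <- spec$component_names
  tibble::as_tibble(as.data.frame(X))
}

#' True weighted quantile indices of a scenario
#'
#' Quantile-scores the concentrations at `spec$q` bins and forms the
#' per-group weighted sums under the scenario's true weights.
#'
#' @param X Concentration tibble from [generate_concentrations()].
#' @param spec The [scenario_spec()].
#' @return A tibble with one true-index column per group.
#' @export
true_indices <- function(X, spec) {
  scores <- score_quantiles(X, q = spec$q)
  wtbl <- tibble::tibble(component = spec$component_names,
                         weight = unname(spec$true_weights))
  construct_indices(scores, spec$groups, wtbl)
}

#' Generate a case-balanced binary outcome
#'
#' The outcome follows `logit p = beta0* + sum_j beta_j* WQSj*` with the
#' intercept centering the linear predictor
#' (`beta0* = -sum_j beta_j* (q - 1)/2`) so the expected case fraction is
#' near one half; outcome vectors are redrawn (concentrations fixed) until
#' the realized case fraction lies in `[0.40, 0.60]`.
#'
#' @param spec The [scenario_spec()].
#' @param idx True-index tibble from [true_indices()].
#' @param seed Integer seed.
#' @return A list: `y` (0/1 vector), `case_fraction`, `eta`, `redraws`.
#' @export
generate_outcome <- function(spec, idx, seed = 1L) {
  beta <- spec$true_beta
  beta0 <- -sum(beta) * (spec$q - 1) / 2
  eta <- beta0 + drop(as.matrix(idx) %*% beta)
  p <- plogis(eta)
  with_local_seed(seed, {
    redraws <- 0L
    repeat {
      y <- rbinom(length(p), 1L, p)
      cf <- mean(y)
      if (cf >= 0.40 && cf <= 0.60) break
      redraws <- redraws + 1L
      if (redraws > 1000L) {
        abort("case fraction never reached [0.40, 0.60]; check the design")
      }
    }
    list(y = y, case_fraction = cf, eta = eta, redraws = redraws)
  })
}

#' Simulate one complete scenario dataset
#'
#' @inheritParams generate_concentrations
#' @param scenario,strength,correlation,n,q Passed to [scenario_spec()]
#'   (alternatively supply a ready `spec`).
#' @param spec Optional [scenario_spec()] overriding the individual fields.
#' @return A list of class `"mixture_sim"`: `data` (tibble of component
#'   columns plus `y`), `groups`, `spec`, `true_indices`, `case_fraction`,
#'   `seed`.
#' @examples
#' sim <- simulate_scenario("A", 2, "W", n = 200, seed = 1)
#' table(sim$data$y)
#' @export
simulate_scenario <- function(scenario = "A", strength = 1L,
                              correlation = "W", n = 1000L, q = 4L,
                              seed = 1L, spec = NULL) {
  if (is.null(spec)) {
    spec <- scenario_spec(scenario, strength, correlation, n = n, q = q)
  }
  X <- generate_concentrations(spec, seed = seed)
  idx <- true_indices(X, spec)
  out <- generate_outcome(spec, idx, seed = seed + 500000L)
  data <- dplyr::bind_cols(X, tibble::tibble(y = out$y))
  structure(
    list(data = data, groups = spec$groups, spec = spec,
         true_indices = idx, case_fraction = out$case_fraction,
         redraws = out$redraws, seed = as.integer(seed)),
    class = "mixture_sim")
}

#' @export
print.mixture_sim <- function(x, ...) {
  cat("Simulated mixture dataset: scenario ", x$spec$scenario,
      ", strength ", x$spec$strength, ", correlation ", x$spec$correlation,
      "\n  n = ", nrow(x$data), ", case fraction = ",
      round(x$case_fraction, 3), "\n", sep = "")
  invisible(x)
}
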