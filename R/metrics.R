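# Replicate-level and aggregate performance metrics, and the Monte-Carlo
# study driver that benchmarks the index and penalized methods across
# simulated scenarios.

#' Sensitivity and specificity of component identification
#'
#' A component is flagged important when its statistic (an averaged index
#' weight, or a penalized coefficient magnitude) meets its threshold
#' (`>=`). Sensitivity is the fraction of truly important components
#' flagged; specificity the fraction of truly unimportant components not
#' flagged.
#'
#' @param values Numeric vector per component (weights, or `abs(coef)`).
#' @param important Logical truth flags, aligned with `values`.
#' @param threshold Scalar or per-component vector of flagging thresholds
#'   (`1/Cj` for index weights, `1e-4` for penalized coefficients).
#' @return A tibble with `sensitivity` and `specificity` (either is `NA`
#'   when its denominator class is empty).
#' @export
classification_metrics <- function(values, important, threshold) {
  stopifnot(length(values) == length(important))
  flag <- values >= threshold
  tibble::tibble(
    sensitivity = if (any(important)) mean(flag[important]) else NA_real_,
    specificity = if (any(!important)) mean(!flag[!important]) else NA_real_)
}

#' Bias and mean squared error of group effect estimates
#'
#' For index methods the estimates are per-replicate group log odds ratios
#' compared against the true group log odds ratio (the odds-ratio scale is
#' available but asymmetric).
#'
#' @param estimates Per-replicate estimates for one group (log-OR scale
#'   unless `scale = "or"`, in which case both estimates and truth are ORs).
#' @param truth The true value on the same scale.
#' @param scale `"log_or"` (default) or `"or"`.
#' @return A tibble with `bias`, `mse` and the replicate count `r`.
#' @export
effect_metrics <- function(estimates, truth, scale = c("log_or", "or")) {
  scale <- match.arg(scale)
  estimates <- estimates[is.finite(estimates)]
  tibble::tibble(bias = mean(estimates) - truth,
                 mse = mean((estimates - truth)^2),
                 r = length(estimates))
}

#' Bias and MSE of penalized coefficients against the weighted truth
#'
#' Penalized fits carry no group coefficient, so each component coefficient
#' is compared with its share of the true group effect,
#' `beta_j* x w_ji*`, and the squared errors and deviations are averaged
#' per group.
#'
#' @param coef_list List (one element per replicate) of per-component
#'   coefficient vectors aligned with `groups`.
#' @param spec The generating [scenario_spec()] (provides true betas and
#'   weights).
#' @return A tibble with `group`, `bias`, `mse`.
#' @export
effect_metrics_penalized <- function(coef_list, spec) {
  groups <- spec$groups
  truth <- spec$true_beta[as.integer(groups$group)] * spec$true_weights
  M <- do.call(rbind, coef_list)  # R x C
  err <- sweep(M, 2L, truth)
  gidx <- as.integer(groups$group)
  out <- lapply(seq_along(attr(groups, "sizes")), function(j) {
    e <- err[, gidx == j, drop = FALSE]
    tibble::tibble(group = attr(groups, "group_names")[j],
                   bias = mean(e), mse = mean(e^2))
  })
  dplyr::bind_rows(out)
}

#' Proportion of replicates rejecting at level alpha
#'
#' Under an effectful group this is the empirical power; under a null group
#' it is the type-I error rate.
#'
#' @param p_values Per-replicate p-values for one group.
#' @param alpha Significance level (0.05 in the study design).
#' @return A single proportion.
#' @export
power_estimate <- function(p_values, alpha = 0.05) {
  mean(p_values < alpha, na.rm = TRUE)
}

#' Akaike information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @return `2 * k - 2 * loglik`.
#' @export
aic_score <- function(loglik, k) {
  if (k < 1) abort("`k` must be >= 1")
  2 * k - 2 * loglik
}

method_choices <- function() c("gwqs", "wqs", "lasso", "group_mcp")

# One replicate of one method on one simulated dataset. Returns a tibble
# with one row per group (plus "overall" where the method reports only an
# overall effect).
run_replicate_method <- function(method, sim, rep_seed, b = 100L, q = 4,
                                 alpha = 0.05) {
  spec <- sim$spec
  groups <- sim$groups
  gnames <- attr(groups, "group_names")
  sizes <- attr(groups, "sizes")
  thr_w <- (1 / sizes)[as.integer(groups$group)]
  if (method == "gwqs") {
    fit <- gwqs(sim$data, groups, outcome = "y", q = q, b = b,
                seed = rep_seed)
    co <- fit$validation$coefficients
    co <- co[match(gnames, co$term), ]
    cm <- classification_metrics(fit$weights$weight, spec$important, thr_w)
    tibble::tibble(method = method, group = gnames,
                   log_or = co$estimate, odds_ratio = co$odds_ratio,
                   p_value = co$p_value,
                   lower = NA_real_, upper = NA_real_,
                   sensitivity = cm$sensitivity,
                   specificity = cm$specificity,
                   aic = fit$validation$aic)
  } else if (method == "wqs") {
    fit <- wqs(sim$data, components = spec$component_names, outcome = "y",
               q = q, b = b, seed = rep_seed)
    co <- fit$validation$coefficients
    co <- co[co$term == "mixture", ]
    w <- fit$weights$weight[match(groups$component, fit$weights$component)]
    cm <- classification_metrics(w, spec$important,
                                 1 / length(spec$component_names))
    # the single index cannot distinguish groups: its one estimate and
    # p-value stand in for every group
    tibble::tibble(method = method, group = gnames,
                   log_or = co$estimate, odds_ratio = co$odds_ratio,
                   p_value = co$p_value,
                   lower = NA_real_, upper = NA_real_,
                   sensitivity = cm$sensitivity,
                   specificity = cm$specificity,
                   aic = fit$validation$aic)
  } else {
    fit <- if (method == "lasso") {
      fit_lasso(sim$data, outcome = "y",
                components = spec$component_names, q = q, seed = rep_seed)
    } else {
      fit_group_mcp(sim$data, groups, outcome = "y", q = q, seed = rep_seed)
    }
    cm <- classification_metrics(abs(fit$coefficients$estimate),
                                 spec$important, 1e-4)
    ind <- power_indicators(fit, sim$data, groups, outcome = "y", q = q,
                            alpha = alpha)
    aic <- aic_score(fit$loglik, fit$df + 1L)
    if (method == "lasso") {
      eff <- summed_effect(fit)
      tibble::tibble(method = method, group = c(gnames, "overall"),
                     log_or = c(rep(NA_real_, length(gnames)), eff$log_or),
                     odds_ratio = c(rep(NA_real_, length(gnames)),
                                    eff$odds_ratio),
                     p_value = NA_real_,
                     lower = c(ind$lower, NA_real_),
                     upper = c(ind$upper, NA_real_),
                     sensitivity = cm$sensitivity,
                     specificity = cm$specificity,
                     aic = aic)
    } else {
      eff <- summed_effect(fit, groups)
      eff <- eff[match(gnames, as.character(eff$group)), ]
      tibble::tibble(method = method, group = gnames,
                     log_or = eff$log_or, odds_ratio = eff$odds_ratio,
                     p_value = NA_real_,
                     lower = ind$lower, upper = ind$upper,
                     sensitivity = cm$sensitivity,
                     specificity = cm$specificity,
                     aic = aic)
    }
  }
}

#' Run the Monte-Carlo simulation study
#'
#' Simulates `reps` datasets per requested condition and fits each
#' requested method, collecting per-replicate group effect estimates,
#' p-values (index methods), power-bound indicators (penalized methods),
#' sensitivity, specificity and AIC. Replicate `r` of every condition uses
#' dataset seed `base_seed + r`, so the study is reproducible and can be
#' resumed or parallelized by replicate without changing results.
#'
#' @param conditions A data frame with columns `scenario`, `strength`,
#'   `correlation` (e.g. a filtered [scenario_catalog()]), or `NULL` for
#'   the full catalog.
#' @param methods Subset of `c("gwqs", "wqs", "lasso", "group_mcp")`.
#' @param reps Number of replicate datasets per condition.
#' @param base_seed Integer base seed.
#' @param n Subjects per dataset.
#' @param b Bootstrap samples for the index methods.
#' @param q Quantile bins.
#' @param alpha Significance level for power.
#' @return An object of class `"simulation_study"`: a list with
#'   `replicates` (long tibble, one row per condition x replicate x method
#'   x group) and `exclusions` (failed replicate/method combinations).
#' @export
run_simulation_study <- function(conditions = NULL,
                                 methods = method_choices(),
                                 reps = 100L, base_seed = 1L,
                                 n = 1000L, b = 100L, q = 4,
                                 alpha = 0.05) {
  methods <- match.arg(methods, method_choices(), several.ok = TRUE)
  if (is.null(conditions)) conditions <- scenario_catalog(n = n, q = q)
  rows <- list(); excl <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    spec <- scenario_spec(cond$scenario, cond$strength, cond$correlation,
                          n = n, q = q)
    for (r in seq_len(reps)) {
      rep_seed <- base_seed + r
      sim <- simulate_scenario(spec = spec, seed = rep_seed)
      for (m in methods) {
        res <- tryCatch(
          run_replicate_method(m, sim, rep_seed, b = b, q = q,
                               alpha = alpha),
          error = function(e) e)
        if (inherits(res, "error")) {
          excl[[length(excl) + 1L]] <- tibble::tibble(
            scenario = cond$scenario, strength = cond$strength,
            correlation = cond$correlation, method = m, rep = r,
            message = conditionMessage(res))
        } else {
          res$scenario <- cond$scenario
          res$strength <- cond$strength
          res$correlation <- cond$correlation
          res$rep <- r
          res$seed <- rep_seed
          res$case_fraction <- sim$case_fraction
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  structure(
    list(replicates = dplyr::bind_rows(rows),
         exclusions = dplyr::bind_rows(excl),
         config = list(methods = methods, reps = reps,
                       base_seed = base_seed, n = n, b = b, q = q,
                       alpha = alpha)),
    class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("Simulation study: ", nrow(x$replicates), " result rows, ",
      x$config$reps, " replicates, methods: ",
      paste(x$config$methods, collapse = ", "), "\n", sep = "")
  if (nrow(x$exclusions)) {
    cat("  excluded replicate fits: ", nrow(x$exclusions), "\n", sep = "")
  }
  invisible(x)
}

study_replicates <- function(study) {
  if (inherits(study, "simulation_study")) study$replicates else study
}

#' Mean estimated group odds ratios by condition and method
#'
#' The effect-estimate summary of the study (one row per condition, group
#' and method; the lasso contributes its overall summed effect).
#'
#' @param study A `"simulation_study"` (or its `replicates` tibble).
#' @return A tibble with mean `odds_ratio`, mean `log_or`, and `bias`/`mse`
#'   of the log odds ratio against the generating truth, plus `r`.
#' @export
summarize_effects <- function(study) {
  reps <- study_replicates(study)
  reps <- reps[!is.na(reps$odds_ratio), ]
  out <- dplyr::summarise(
    dplyr::group_by(reps, .data$scenario, .data$strength, .data$correlation,
                    .data$method, .data$group),
    odds_ratio = mean(.data$odds_ratio),
    log_or = mean(.data$log_or),
    r = dplyr::n(), .groups = "drop")
  truth <- truth_table()
  out <- dplyr::left_join(out, truth,
                          by = c("scenario", "strength", "group"))
  reps2 <- dplyr::left_join(reps, truth,
                            by = c("scenario", "strength", "group"))
  errs <- dplyr::summarise(
    dplyr::group_by(reps2, .data$scenario, .data$strength,
                    .data$correlation, .data$method, .data$group),
    bias = mean(.data$log_or - .data$true_log_or),
    mse = mean((.data$log_or - .data$true_log_or)^2), .groups = "drop")
  dplyr::left_join(out, errs,
                   by = c("scenario", "strength", "correlation", "method",
                          "group"))
}

# True group log odds ratios for every scenario/strength; the lasso's
# overall row compares against the sum of the group effects.
truth_table <- function() {
  grid <- tidyr::expand_grid(scenario = c("A", "B", "C"), strength = 1:5)
  purrr::pmap_dfr(grid, function(scenario, strength) {
    spec <- scenario_spec(scenario, strength, "W")
    tibble::tibble(scenario = scenario, strength = strength,
                   group = c(names(spec$true_beta), "overall"),
                   true_or = c(unname(spec$true_or),
                               exp(sum(spec$true_beta))),
                   true_log_or = c(unname(spec$true_beta),
                                   sum(spec$true_beta)))
  })
}

#' Power (or type-I error) by condition, method and group
#'
#' Index methods: proportion of replicates with the group's validation
#' p-value below alpha. Penalized methods: the lower/upper power bounds.
#'
#' @inheritParams summarize_effects
#' @param alpha Significance level.
#' @return A tibble with `power` (index methods) and `lower`/`upper`
#'   (penalized methods).
#' @export
summarize_power <- function(study, alpha = 0.05) {
  reps <- study_replicates(study)
  reps <- reps[reps$group != "overall", ]
  dplyr::summarise(
    dplyr::group_by(reps, .data$scenario, .data$strength, .data$correlation,
                    .data$method, .data$group),
    power = if (all(is.na(.data$p_value))) NA_real_ else
      power_estimate(.data$p_value, alpha),
    lower = if (all(is.na(.data$lower))) NA_real_ else
      mean(.data$lower, na.rm = TRUE),
    upper = if (all(is.na(.data$upper))) NA_real_ else
      mean(.data$upper, na.rm = TRUE),
    r = dplyr::n(), .groups = "drop")
}

#' Mean sensitivity and specificity by condition and method
#'
#' @inheritParams summarize_effects
#' @return A tibble with mean `sensitivity` and `specificity` per
#'   condition and method (replicate-level values are already pooled over
#'   components).
#' @export
summarize_classification <- function(study) {
  reps <- study_replicates(study)
  reps <- reps[reps$group != "overall", ]
  first <- dplyr::distinct(reps, .data$scenario, .data$strength,
                           .data$correlation, .data$method, .data$rep,
                           .keep_all = TRUE)
  dplyr::summarise(
    dplyr::group_by(first, .data$scenario, .data$strength,
                    .data$correlation, .data$method),
    sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    specificity = mean(.data$specificity, na.rm = TRUE),
    r = dplyr::n(), .groups = "drop")
}

#' Mean AIC by condition and method
#'
#' Index methods report the validation GLM's AIC; penalized methods the
#' AIC of the penalized fit with `df + 1` parameters. Absolute values are
#' therefore comparable within, not across, those two families; the
#' within-study ordering is the quantity of interest.
#'
#' @inheritParams summarize_effects
#' @return A tibble with mean `aic` per condition and method.
#' @export
summarize_aic <- function(study) {
  reps <- study_replicates(study)
  first <- dplyr::distinct(reps, .data$scenario, .data$strength,
                           .data$correlation, .data$method, .data$rep,
                           .keep_all = TRUE)
  dplyr::summarise(
    dplyr::group_by(first, .data$scenario, .data$strength,
                    .data$correlation, .data$method),
    aic = mean(.data$aic), r = dplyr::n(), .groups = "drop")
}
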