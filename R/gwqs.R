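#' Grouped weighted quantile sum regression
#'
#' End-to-end GWQS fit for a binary outcome: quantile-score the exposure
#' components, split subjects into training and validation halves, estimate
#' simplex-constrained component weights on bootstrap resamples of the
#' training half, combine them by test-statistic-weighted averaging, build
#' one weighted index per group, and fit the unconstrained validation GLM
#' that provides the inferential odds ratio, confidence interval and
#' p-value for each group.
#'
#' @param data A data frame with one column per exposure component plus the
#'   outcome (and any covariate) columns.
#' @param groups Component-to-group assignment accepted by
#'   [group_structure()]: a named list of component names or a
#'   `component`/`group` data frame.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param covariates Optional character vector of covariate column names.
#' @param q Number of quantile bins (default quartiles).
#' @param b Number of bootstrap samples (default 100).
#' @param split_fraction Training fraction of the half split (default 0.5).
#' @param seed Integer seed controlling the split and the bootstrap.
#' @param quantile_scope `"full"` computes quantile cut points on all
#'   subjects before the split (the default); `"train"` learns them on the
#'   training half and reuses them for validation subjects via the training
#'   rank distribution.
#' @param beta_signs Optional `-1`/`+1` per group constraining coefficient
#'   directions during training; unconstrained by default.
#' @param tol,max_iterations Solver controls, see [fit_constrained_mle()].
#' @return An object of class `"gwqs_fit"` with elements `weights`
#'   (tibble: group, component, weight), `validation`
#'   (a `"validation_fit"`), `groups`, `config`, and `diagnostics`
#'   (per-bootstrap convergence, coefficients and test statistics).
#' @examples
#' sim <- simulate_scenario("A", strength = 3, correlation = "W",
#'                          n = 300, seed = 7)
#' fit <- gwqs(sim$data, sim$groups, outcome = "y", b = 5, seed = 1)
#' tidy(fit)
#' @export
gwqs <- function(data, groups, outcome = "y", covariates = NULL,
                 q = 4, b = 100L, split_fraction = 0.5, seed = 1L,
                 quantile_scope = c("full", "train"),
                 beta_signs = NULL, tol = 1e-8, max_iterations = 500L) {
  quantile_scope <- match.arg(quantile_scope)
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column not found: ", outcome))
  }
  groups <- group_structure(groups)
  comp_names <- groups$component
  missing <- setdiff(comp_names, names(data))
  if (length(missing)) {
    abort(paste0("component columns missing from data: ",
                 paste(missing, collapse = ", ")))
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) {
    abort(paste0("outcome column `", outcome, "` must be coded 0/1"))
  }
  Z <- if (length(covariates)) as.matrix(data[covariates])
  n <- nrow(data)
  split <- split_train_validation(n, split_fraction, seed = seed)

  if (quantile_scope == "full") {
    scores <- score_quantiles(data, q = q, components = comp_names)
    scores_train <- scores[split$train, , drop = FALSE]
    scores_valid <- scores[split$validation, , drop = FALSE]
  } else {
    scores_train <- score_quantiles(data[split$train, , drop = FALSE],
                                    q = q, components = comp_names)
    scores_valid <- score_against_training(
      data[split$validation, comp_names, drop = FALSE],
      data[split$train, comp_names, drop = FALSE], q = q)
  }

  fits <- bootstrap_ensemble(
    scores_train, groups,
    covariates = if (!is.null(Z)) Z[split$train, , drop = FALSE],
    y = y[split$train], b = b, seed = seed + 1L,
    tol = tol, max_iterations = max_iterations, beta_signs = beta_signs)
  n_conv <- sum(vapply(fits, `[[`, logical(1), "converged"))
  if (n_conv < b / 2) {
    abort(paste0("only ", n_conv, " of ", b, " bootstrap fits converged"))
  }
  weights <- average_weights(fits, groups)
  idx_valid <- construct_indices(scores_valid, groups, weights)
  validation <- fit_validation_glm(
    idx_valid,
    covariates = if (!is.null(Z)) Z[split$validation, , drop = FALSE],
    y = y[split$validation])

  boot_tbl <- tibble::tibble(
    bootstrap = seq_along(fits),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"))
  betas <- do.call(rbind, lapply(fits, `[[`, "beta"))
  tstats <- do.call(rbind, lapply(fits, `[[`, "test_stats"))
  colnames(betas) <- paste0("beta_", attr(groups, "group_names"))
  colnames(tstats) <- paste0("t_", attr(groups, "group_names"))
  boot_tbl <- dplyr::bind_cols(boot_tbl,
                               tibble::as_tibble(as.data.frame(betas)),
                               tibble::as_tibble(as.data.frame(tstats)))

  structure(
    list(weights = weights,
         validation = validation,
         groups = groups,
         split = split,
         config = list(q = q, b = b, split_fraction = split_fraction,
                       seed = seed, quantile_scope = quantile_scope,
                       outcome = outcome, covariates = covariates,
                       beta_signs = beta_signs, tol = tol,
                       max_iterations = max_iterations),
         diagnostics = list(bootstrap = boot_tbl, n_converged = n_conv)),
    class = "gwqs_fit")
}

# Score validation rows against cut points learned on training data:
# each value is placed by the proportion of training values below it.
score_against_training <- function(newdata, traindata, q) {
  scores <- mapply(function(xn, xt) {
    rt <- rank(xt, ties.method = "average")
    cuts <- quantile(rt, probs = seq_len(q - 1L) / q, names = FALSE)
    rn <- vapply(xn, function(v) {
      sum(xt < v) + (sum(xt == v) + 1) / 2
    }, numeric(1))
    as.integer(vapply(rn, function(ri) sum(ri > cuts), numeric(1)))
  }, as.data.frame(newdata), as.data.frame(traindata))
  out <- tibble::as_tibble(as.data.frame(scores))
  attr(out, "q") <- as.integer(q)
  out
}

#' Classic (single-index) weighted quantile sum regression
#'
#' WQS is the one-group special case of [gwqs()]: all components enter a
#' single weighted index. Identical arguments and return shape.
#'
#' @inheritParams gwqs
#' @param components Character vector of exposure columns; defaults to every
#'   column except the outcome and covariates.
#' @export
wqs <- function(data, components = NULL, outcome = "y", covariates = NULL,
                q = 4, b = 100L, split_fraction = 0.5, seed = 1L,
                quantile_scope = c("full", "train"),
                beta_signs = NULL, tol = 1e-8, max_iterations = 500L) {
  data <- as.data.frame(data)
  if (is.null(components)) {
    components <- setdiff(names(data), c(outcome, covariates))
  }
  gwqs(data, groups = list(mixture = components), outcome = outcome,
       covariates = covariates, q = q, b = b,
       split_fraction = split_fraction, seed = seed,
       quantile_scope = quantile_scope, beta_signs = beta_signs,
       tol = tol, max_iterations = max_iterations)
}

#' @export
print.gwqs_fit <- function(x, ...) {
  sizes <- attr(x$groups, "sizes")
  cat("Grouped weighted quantile sum regression\n")
  cat("  groups: ", paste0(attr(x$groups, "group_names"), " (",
                           sizes, ")", collapse = ", "), "\n", sep = "")
  cat("  bootstraps: ", x$config$b, " (", x$diagnostics$n_converged,
      " converged), q = ", x$config$q, "\n", sep = "")
  cat("  validation n = ", x$validation$n,
      ", AIC = ", round(x$validation$aic, 2), "\n\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy the validation coefficients of a GWQS fit
#'
#' @param x A `"gwqs_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per validation-model term: `term`,
#'   `estimate` (log odds), `std_error`, `odds_ratio`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
tidy.gwqs_fit <- function(x, ...) x$validation$coefficients

#' One-row summary of a GWQS fit
#'
#' @param x A `"gwqs_fit"`.
#' @param ... Unused.
#' @return A tibble with `n_validation`, `loglik`, `aic`, `b`,
#'   `n_converged`, `converged`.
#' @export
glance.gwqs_fit <- function(x, ...) {
  tibble::tibble(
    n_validation = x$validation$n,
    loglik = x$validation$loglik,
    aic = x$validation$aic,
    b = x$config$b,
    n_converged = x$diagnostics$n_converged,
    converged = x$validation$converged)
}

#' Extract the averaged component weights
#'
#' @param object A `"gwqs_fit"`.
#' @param ... Unused.
#' @return The `"ensemble_weights"` tibble (group, component, weight).
#' @export
weights.gwqs_fit <- function(object, ...) object$weights

#' @export
tidy.validation_fit <- function(x, ...) x$coefficients

#' @export
glance.validation_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, aic = x$aic, n = x$n,
                 converged = x$converged)
}
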