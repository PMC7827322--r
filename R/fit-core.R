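# Core estimation machinery for grouped weighted quantile sum regression.
#
# The model for a binary outcome y is
#   logit P(y = 1) = beta0 + sum_j beta_j * (sum_i w_ji * q_ji) + z' phi
# with, within every group j, weights w_ji in [0, 1] summing to 1.
#
# The simplex constraint is enforced exactly through a per-group softmax
# reparameterization (the first component of each group anchors the
# identifiability); the resulting smooth unconstrained problem is solved by
# BFGS with analytic gradients.

log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 18
  out[hi] <- x[hi] + exp(-x[hi])
  out[!hi] <- log1p(exp(x[!hi]))
  out
}

# Precompute the index bookkeeping shared by every objective evaluation.
# scores columns are reordered to the group map's component order.
prep_fit_data <- function(scores, groups, covariates = NULL, y = NULL) {
  groups <- group_structure(groups)
  Qm <- as.matrix(scores)
  missing <- setdiff(groups$component, colnames(Qm))
  if (length(missing)) {
    abort(paste0("score columns missing for components: ",
                 paste(missing, collapse = ", ")))
  }
  Qm <- Qm[, groups$component, drop = FALSE]
  gidx <- as.integer(groups$group)
  J <- nlevels(groups$group)
  first_of_group <- match(seq_len(J), gidx)
  theta_free <- setdiff(seq_along(gidx), first_of_group)
  Z <- if (is.null(covariates)) {
    matrix(0, nrow(Qm), 0L)
  } else {
    as.matrix(covariates)
  }
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) abort("outcome must be coded 0/1")
  }
  list(Qm = Qm, Z = Z, y = y, groups = groups, gidx = gidx, J = J,
       K = ncol(Z), C = ncol(Qm),
       first_of_group = first_of_group, theta_free = theta_free,
       group_names = attr(groups, "group_names"),
       sizes = attr(groups, "sizes"))
}

# Map free softmax parameters to exact simplex weights per group.
theta_to_weights <- function(theta_free_vals, pd) {
  theta <- numeric(pd$C)
  theta[pd$theta_free] <- theta_free_vals
  w <- numeric(pd$C)
  for (j in seq_len(pd$J)) {
    sel <- pd$gidx == j
    e <- exp(theta[sel] - max(theta[sel]))
    w[sel] <- e / sum(e)
  }
  w
}

nll_eta <- function(eta, y) sum(log1pexp(eta)) - sum(y * eta)

# Objective and gradient over par = c(beta0, beta[1:J], phi[1:K], theta_free).
make_objective <- function(pd) {
  J <- pd$J; K <- pd$K
  list(
    fn = function(par) {
      beta0 <- par[1L]
      beta <- par[1L + seq_len(J)]
      phi <- par[1L + J + seq_len(K)]
      w <- theta_to_weights(par[-seq_len(1L + J + K)], pd)
      I <- index_matrix(pd, w)
      eta <- beta0 + drop(I %*% beta) + if (K) drop(pd$Z %*% phi) else 0
      nll_eta(eta, pd$y)
    },
    gr = function(par) {
      beta0 <- par[1L]
      beta <- par[1L + seq_len(J)]
      phi <- par[1L + J + seq_len(K)]
      w <- theta_to_weights(par[-seq_len(1L + J + K)], pd)
      I <- index_matrix(pd, w)
      eta <- beta0 + drop(I %*% beta) + if (K) drop(pd$Z %*% phi) else 0
      r <- plogis(eta) - pd$y
      u <- drop(crossprod(pd$Qm, r))          # dL/dw before chain rule
      dtheta <- numeric(pd$C)
      for (j in seq_len(J)) {
        sel <- pd$gidx == j
        gw <- beta[j] * u[sel]
        wj <- w[sel]
        dtheta[sel] <- wj * (gw - sum(wj * gw))
      }
      c(sum(r),
        drop(crossprod(I, r)),
        if (K) drop(crossprod(pd$Z, r)) else numeric(0),
        dtheta[pd$theta_free])
    }
  )
}

# n x J matrix of per-group weighted index values for weight vector w
# (aligned to pd$Qm columns).
index_matrix <- function(pd, w) {
  I <- matrix(0, nrow(pd$Qm), pd$J)
  for (j in seq_len(pd$J)) {
    sel <- pd$gidx == j
    I[, j] <- pd$Qm[, sel, drop = FALSE] %*% w[sel]
  }
  colnames(I) <- pd$group_names
  I
}

#' Negative log-likelihood of the grouped index model
#'
#' Evaluates the negative Bernoulli log-likelihood of the constrained model
#' at an explicit parameter vector `c(beta0, beta[1:J], phi, w[1:C])`, with
#' the component weights `w` supplied directly (non-negative; they are used
#' as given, so feasibility is the caller's responsibility).
#'
#' @param params Numeric vector `c(beta0, beta_1..beta_J, phi, w_1..w_C)`;
#'   the weights are ordered as in `group_structure(groups)$component`.
#' @param scores Quantile-score data (from [score_quantiles()]).
#' @param groups A [group_structure()] (or input accepted by it).
#' @param covariates Optional numeric covariate matrix/data frame.
#' @param y Binary outcome vector (0/1).
#' @return The negative log-likelihood (a single number).
#' @export
gwqs_negloglik <- function(params, scores, groups, covariates = NULL, y) {
  pd <- prep_fit_data(scores, groups, covariates, y)
  expected <- 1L + pd$J + pd$K + pd$C
  if (length(params) != expected) {
    abort(paste0("`params` must have length ", expected,
                 " = 1 + J + ncol(covariates) + C"))
  }
  if (any(!is.finite(params))) abort("`params` must be finite")
  beta0 <- params[1L]
  beta <- params[1L + seq_len(pd$J)]
  phi <- params[1L + pd$J + seq_len(pd$K)]
  w <- params[-seq_len(1L + pd$J + pd$K)]
  if (any(w < 0)) abort("weights must be non-negative")
  I <- index_matrix(pd, w)
  eta <- beta0 + drop(I %*% beta) + if (pd$K) drop(pd$Z %*% phi) else 0
  # clip linear predictor so p never reaches exactly 0 or 1
  eta <- pmin(pmax(eta, -36), 36)
  nll_eta(eta, pd$y)
}

#' Fit the simplex-constrained maximum likelihood estimate
#'
#' Maximizes the grouped-index log-likelihood over the intercept, one
#' coefficient per group index, covariate coefficients, and per-group
#' component weights constrained to the probability simplex. Weights start
#' at `1/Cj` (the simplex center) and all coefficients at zero. Each group
#' coefficient's Wald statistic `t_j = beta_j / SE(beta_j)` is computed from
#' the observed information over `(beta0, beta, phi)` with the weights held
#' at their optima.
#'
#' @inheritParams gwqs_negloglik
#' @param tol Relative convergence tolerance on the objective.
#' @param max_iterations Iteration cap for the optimizer.
#' @param beta_signs Optional numeric vector of `-1`/`+1` per group imposing
#'   the sign of each group coefficient during training (`NULL`, the
#'   default, leaves directions unconstrained).
#' @return A list of class `"gwqs_mle"`: `weights` (named, simplex per
#'   group), `beta0`, `beta`, `phi`, `test_stats`, `se_beta`, `loglik`,
#'   `converged`, `counts`.
#' @export
fit_constrained_mle <- function(scores, groups, covariates = NULL, y,
                                tol = 1e-8, max_iterations = 500L,
                                beta_signs = NULL) {
  pd <- prep_fit_data(scores, groups, covariates, y)
  if (length(unique(pd$y)) < 2L) abort("outcome must contain both classes")
  obj <- if (is.null(beta_signs)) {
    make_objective(pd)
  } else {
    make_signed_objective(pd, beta_signs)
  }
  n_par <- 1L + pd$J + pd$K + (pd$C - pd$J)
  par0 <- numeric(n_par)
  if (!is.null(beta_signs)) {
    par0[1L + seq_len(pd$J)] <- -5  # softplus scale: near-zero magnitudes
  }
  fit <- optim(par0, fn = obj$fn, gr = obj$gr, method = "BFGS",
               control = list(maxit = max_iterations, reltol = tol))
  beta0 <- fit$par[1L]
  beta_raw <- fit$par[1L + seq_len(pd$J)]
  beta <- if (is.null(beta_signs)) beta_raw else beta_signs * log1pexp(beta_raw)
  phi <- fit$par[1L + pd$J + seq_len(pd$K)]
  w <- theta_to_weights(fit$par[-seq_len(1L + pd$J + pd$K)], pd)
  # exact renormalization per group (softmax is already exact up to fp error)
  for (j in seq_len(pd$J)) {
    sel <- pd$gidx == j
    w[sel] <- w[sel] / sum(w[sel])
  }
  names(w) <- colnames(pd$Qm)
  I <- index_matrix(pd, w)
  X1 <- cbind(`(Intercept)` = 1, I, pd$Z)
  eta <- drop(X1 %*% c(beta0, beta, phi))
  p <- plogis(eta)
  info <- crossprod(X1 * (p * (1 - p)), X1)
  se_beta <- rep(NA_real_, pd$J)
  tstat <- rep(NA_real_, pd$J)
  ok <- fit$convergence == 0L
  covm <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(covm) || any(!is.finite(diag(covm))) || any(diag(covm) <= 0)) {
    ok <- FALSE
  } else {
    se_beta <- sqrt(diag(covm))[1L + seq_len(pd$J)]
    tstat <- beta / se_beta
    if (any(!is.finite(tstat))) ok <- FALSE
  }
  structure(
    list(weights = w, beta0 = beta0, beta = setNames(beta, pd$group_names),
         phi = phi, test_stats = setNames(tstat, pd$group_names),
         se_beta = se_beta, loglik = -fit$value,
         converged = ok, counts = fit$counts),
    class = "gwqs_mle")
}

# Variant objective with beta_j = sign_j * softplus(gamma_j).
make_signed_objective <- function(pd, beta_signs) {
  if (length(beta_signs) != pd$J || !all(beta_signs %in% c(-1, 1))) {
    abort("`beta_signs` must be -1/+1 per group")
  }
  J <- pd$J; K <- pd$K
  base <- make_objective(pd)
  list(
    fn = function(par) {
      gamma <- par[1L + seq_len(J)]
      par2 <- par
      par2[1L + seq_len(J)] <- beta_signs * log1pexp(gamma)
      base$fn(par2)
    },
    gr = function(par) {
      gamma <- par[1L + seq_len(J)]
      par2 <- par
      par2[1L + seq_len(J)] <- beta_signs * log1pexp(gamma)
      g <- base$gr(par2)
      g[1L + seq_len(J)] <- g[1L + seq_len(J)] * beta_signs * plogis(gamma)
      g
    }
  )
}

#' Bootstrap ensemble of constrained fits
#'
#' Draws `b` bootstrap resamples of the training data (independent uniform
#' draws with replacement; resamples missing an outcome class are redrawn,
#' up to 100 times) and fits the constrained MLE on each.
#'
#' @inheritParams fit_constrained_mle
#' @param b Number of bootstrap samples.
#' @param seed Integer seed; the resample sequence is deterministic given it.
#' @param resample Diagnostic flag; `FALSE` fits each replicate on the
#'   training data itself (no resampling).
#' @return A list of `b` `"gwqs_mle"` fits.
#' @export
bootstrap_ensemble <- function(scores, groups, covariates = NULL, y,
                               b = 100L, seed = 1L, resample = TRUE,
                               tol = 1e-8, max_iterations = 500L,
                               beta_signs = NULL) {
  if (b < 1L) abort("`b` must be >= 1")
  pd <- prep_fit_data(scores, groups, covariates, y)
  n <- nrow(pd$Qm)
  scores_m <- tibble::as_tibble(as.data.frame(pd$Qm))
  fits <- with_local_seed(seed, {
    lapply(seq_len(b), function(bi) {
      if (resample) {
        idx <- sample.int(n, n, replace = TRUE)
        tries <- 0L
        while (length(unique(pd$y[idx])) < 2L) {
          tries <- tries + 1L
          if (tries > 100L) abort("could not draw a resample with both classes")
          idx <- sample.int(n, n, replace = TRUE)
        }
      } else {
        idx <- seq_len(n)
      }
      fit_constrained_mle(
        scores_m[idx, , drop = FALSE], groups,
        covariates = if (pd$K) pd$Z[idx, , drop = FALSE],
        y = pd$y[idx], tol = tol, max_iterations = max_iterations,
        beta_signs = beta_signs)
    })
  })
  n_conv <- sum(vapply(fits, `[[`, logical(1), "converged"))
  if (n_conv == 0L) {
    abort("no bootstrap fit converged; consider loosening `tol`")
  }
  fits
}

#' Average bootstrap weights with test-statistic weighting
#'
#' Combines converged bootstrap fits into final component weights
#' `wbar_ji = sum_b w_jib * |t_jb| / sum_b |t_jb|` per group; groups whose
#' test statistics are all zero fall back to the unweighted mean (with a
#' warning).
#'
#' @param fits List of `"gwqs_mle"` fits from [bootstrap_ensemble()].
#' @param groups The [group_structure()] used for fitting.
#' @return A tibble of class `"ensemble_weights"` with columns `group`,
#'   `component`, `weight`; attribute `n_fits` gives the per-group count of
#'   converged fits used.
#' @export
average_weights <- function(fits, groups) {
  groups <- group_structure(groups)
  keep <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(keep)) abort("no converged fits to average")
  fits <- fits[keep]
  W <- do.call(rbind, lapply(fits, `[[`, "weights"))  # B x C
  Tm <- abs(do.call(rbind, lapply(fits, `[[`, "test_stats")))  # B x J
  gidx <- as.integer(groups$group)
  wbar <- numeric(ncol(W))
  for (j in seq_len(nlevels(groups$group))) {
    sel <- gidx == j
    tj <- Tm[, j]
    if (sum(tj) <= 0) {
      warn(paste0("all test statistics zero in group ",
                  levels(groups$group)[j], "; using unweighted mean"))
      tj <- rep(1, length(tj))
    }
    wj <- drop(crossprod(W[, sel, drop = FALSE], tj)) / sum(tj)
    wbar[sel] <- wj / sum(wj)
  }
  out <- tibble::tibble(group = groups$group,
                        component = groups$component,
                        weight = wbar)
  attr(out, "n_fits") <- length(fits)
  class(out) <- c("ensemble_weights", class(out))
  out
}

#' Construct per-group weighted quantile sum indices
#'
#' @param scores Quantile scores (from [score_quantiles()]).
#' @param groups A [group_structure()].
#' @param weights An `"ensemble_weights"` tibble (or any tibble with
#'   `component` and `weight` columns covering every component).
#' @return A tibble with one index column per group; each value lies in
#'   `[0, q - 1]`.
#' @export
construct_indices <- function(scores, groups, weights) {
  groups <- group_structure(groups)
  pd <- prep_fit_data(scores, groups)
  w <- weights$weight[match(groups$component, weights$component)]
  if (anyNA(w)) {
    abort(paste0("weights missing for components: ",
                 paste(groups$component[is.na(w)], collapse = ", ")))
  }
  tibble::as_tibble(as.data.frame(index_matrix(pd, w)))
}

#' Fit the validation generalized linear model
#'
#' Unconstrained logistic regression of the held-out outcome on the final
#' group indices (plus covariates), providing the inferential odds ratios,
#' Wald confidence intervals and p-values for each group effect.
#'
#' @param indices Tibble/data frame of index values (one column per group).
#' @param covariates Optional covariate matrix or data frame.
#' @param y Binary outcome (0/1) for the validation subjects.
#' @param ci_level Confidence level for the Wald intervals.
#' @return A list of class `"validation_fit"` with elements `coefficients`
#'   (tibble: term, estimate, std_error, odds_ratio, conf_low, conf_high,
#'   p_value), `loglik`, `aic`, `n`, `converged`, and the underlying `glm`.
#' @export
fit_validation_glm <- function(indices, covariates = NULL, y,
                               ci_level = 0.95) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) abort("validation outcome must contain both classes")
  df <- as.data.frame(indices)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df$.y <- y
  fit <- glm(.y ~ ., data = df, family = binomial(),
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) warn("validation GLM did not converge (possible separation)")
  z <- -qnorm_lower((1 - ci_level) / 2)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    conf_low = exp(unname(est) - z * unname(se)),
    conf_high = exp(unname(est) + z * unname(se)),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se)))
  )
  structure(
    list(coefficients = coefs, loglik = as.numeric(logLik(fit)),
         aic = AIC(fit), n = length(y), converged = fit$converged,
         glm = fit),
    class = "validation_fit")
}

qnorm_lower <- function(p) stats::qnorm(p)
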