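# ggplot2 displays for fitted objects and study summaries.

#' Plot the averaged component weights of a fit
#'
#' Bar chart of the test-statistic-averaged weights per component,
#' faceted by group, with the `1/Cj` importance threshold marked.
#'
#' @param fit A `"gwqs_fit"`.
#' @return A ggplot object.
#' @export
plot_weights <- function(fit) {
  w <- fit$weights
  sizes <- attr(fit$groups, "sizes")
  thr <- tibble::tibble(group = attr(fit$groups, "group_names"),
                        threshold = 1 / sizes)
  ggplot2::ggplot(w, ggplot2::aes(x = stats::reorder(.data$component,
                                                     -.data$weight),
                                  y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = "component", y = "averaged weight") +
    ggplot2::theme_minimal()
}

#' Plot validation odds ratios with confidence intervals
#'
#' A tabular forest-style display: point estimates and 95% intervals per
#' validation-model term on the odds-ratio scale.
#'
#' @param fit A `"gwqs_fit"`.
#' @param terms Optional subset of terms; default drops the intercept.
#' @return A ggplot object.
#' @export
plot_effects <- function(fit, terms = NULL) {
  co <- tidy(fit)
  co <- co[co$term != "(Intercept)", ]
  if (!is.null(terms)) co <- co[co$term %in% terms, ]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_weights
#' @param object A `"gwqs_fit"`.
#' @param type `"weights"` or `"effects"`.
#' @param ... Unused.
#' @export
autoplot.gwqs_fit <- function(object, type = c("weights", "effects"), ...) {
  type <- match.arg(type)
  if (type == "weights") plot_weights(object) else plot_effects(object)
}

#' Plot mean estimated odds ratios across study conditions
#'
#' @param object A `"simulation_study"`.
#' @param ... Unused.
#' @return A ggplot object: estimated versus true group odds ratios by
#'   method, faceted by scenario and correlation.
#' @export
autoplot.simulation_study <- function(object, ...) {
  eff <- summarize_effects(object)
  eff <- eff[!is.na(eff$true_or), ]
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$true_or,
                                    y = .data$odds_ratio,
                                    colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_grid(scenario ~ correlation) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "true group odds ratio",
                  y = "mean estimated odds ratio") +
    ggplot2::theme_minimal()
}
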