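#' Forest plot of pooled correlations
#'
#' One point and interval per fixed-effect term; with `robust = TRUE` the
#' CR2 cluster-robust intervals are overlaid.
#'
#' @param object An `mlmv_fit`.
#' @param robust Overlay cluster-robust intervals.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlmv_fit <- function(object, robust = FALSE, conf.level = 0.95, ...) {
  td <- tidy(object, conf.level = conf.level, back_transform = TRUE)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                        y = stats::reorder(.data$term,
                                                           .data$estimate))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Pooled correlation", y = NULL,
                  title = sprintf("Working model %d (%s)",
                                  object$model$model_id, object$method)) +
    ggplot2::theme_minimal()
  if (robust) {
    rb <- robust_vcov(object, conf.level = conf.level)
    if (object$model$scale == "fisher_z") {
      rb$conf.low <- tanh(rb$conf.low); rb$conf.high <- tanh(rb$conf.high)
      rb$estimate <- tanh(rb$estimate)
    }
    p <- p + ggplot2::geom_errorbarh(
      data = rb,
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high,
                   y = .data$term),
      height = 0.25, colour = "firebrick", inherit.aes = FALSE)
  }
  p
}

#' Sensitivity-sweep plot
#'
#' Mean pooled coefficient (or a heterogeneity summary) against the fixed
#' within-study random-effect correlation, faceted by the between-study value
#' and scale, one line per working model.
#'
#' @param object An `mlmv_sweep` from [sensitivity_sweep()].
#' @param what Column to plot: `"mean_pooled"` (default), `"mean_tau2"`,
#'   `"mean_gamma2"`, `"BIC"`, ...
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlmv_sweep <- function(object, what = "mean_pooled", ...) {
  stopifnot(what %in% names(object))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rho, y = .data[[what]],
                               colour = factor(.data$model),
                               group = factor(.data$model))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(scale ~ phi,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(rho), y = what, colour = "Model") +
    ggplot2::theme_minimal()
}

#' Information-criterion plot for a decision-scheme run
#'
#' @param object An `mlmv_decision` from [run_decision_scheme()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlmv_decision <- function(object, ...) {
  tab <- tidyr::pivot_longer(
    dplyr::select(object$ic_table, "model", "AIC", "BIC", "AICc"),
    cols = c("AIC", "BIC", "AICc"), names_to = "criterion",
    values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$model), y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "Working model", y = "Information criterion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
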