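#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a fitted model
#'
#' One row per fixed-effect term with the pooled estimate, model-based
#' standard error, z statistic, two-sided normal p-value and Wald confidence
#' interval. On the Fisher-z scale, `back_transform = TRUE` maps estimates and
#' CI endpoints back to the correlation metric via `tanh` (standard errors
#' stay on the z scale).
#'
#' @param x An `mlmv_fit` object.
#' @param conf.level Confidence level (default 0.95).
#' @param back_transform Back-transform Fisher-z estimates to correlations.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.mlmv_fit <- function(x, conf.level = 0.95, back_transform = FALSE, ...) {
  se <- sqrt(diag(x$vcov_beta))
  z <- x$beta / se
  crit <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z))),
    conf.low = unname(x$beta - crit * se),
    conf.high = unname(x$beta + crit * se)
  )
  if (back_transform && x$model$scale == "fisher_z") {
    out$estimate <- tanh(out$estimate)
    out$conf.low <- tanh(out$conf.low)
    out$conf.high <- tanh(out$conf.high)
  }
  out
}

#' Model-level summary of a fitted model
#'
#' @param x An `mlmv_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the log-likelihood, deviance, information
#'   criteria, residual heterogeneity Q test, parameter counts, data sizes
#'   and convergence flag.
#' @export
glance.mlmv_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$model_id, method = x$method, scale = x$model$scale,
    logLik = x$loglik, deviance = x$deviance,
    AIC = x$aic, BIC = x$bic, AICc = x$aicc,
    q_varpar = x$n_varpar, p_fixed = x$p_fixed,
    QE = x$qe, QE_df = x$qe_df, QE_p = x$qe_p,
    nobs = x$nobs, n_samples = x$n_samples, n_studies = x$n_studies,
    converged = x$converged
  )
}

#' @export
print.mlmv_fit <- function(x, ...) {
  cat(sprintf("Multilevel multivariate meta-analysis (%s, %s scale)\n",
              x$method, x$model$scale))
  cat(sprintf("  Model %d: within %s (rho = %g), between %s (phi = %g)\n",
              x$model$model_id, x$model$within, x$model$rho,
              x$model$between, x$model$phi))
  cat(sprintf("  %d rows, %d samples, %d studies; logLik = %.4f, AIC = %.2f, BIC = %.2f\n",
              x$nobs, x$n_samples, x$n_studies, x$loglik, x$aic, x$bic))
  cat(sprintf("  Q(%d) = %.2f, p %s\n", x$qe_df, x$qe,
              format.pval(x$qe_p, digits = 3)))
  cat("\nVariance components:\n")
  cat("  tau^2 (within): ", paste(sprintf("%s = %.5f", names(x$tau2), x$tau2),
                                  collapse = ", "), "\n")
  cat("  gamma^2 (between): ", paste(sprintf("%s = %.5f", names(x$gamma2),
                                             x$gamma2), collapse = ", "), "\n")
  if (any(x$boundary)) {
    cat("  (", sum(x$boundary), "variance component(s) at the zero boundary )\n")
  }
  cat("\nPooled coefficients:\n")
  print(tidy(x), n = min(length(x$beta), 25))
  if (!x$converged) cat("\nWARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.mlmv_fit <- function(object, ...) object$beta

#' @export
vcov.mlmv_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.mlmv_fit <- function(object, ...) {
  structure(object$loglik, df = object$q_params, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.mlmv_fit <- function(object, ...) object$nobs
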