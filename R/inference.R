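#' Cluster-robust (sandwich) inference with studies as clusters
#'
#' Robust standard errors for the pooled coefficients that do not rely on the
#' working model's dependence structure being correct. The sandwich meat is
#' accumulated per primary study. `CR0` is the unadjusted estimator; `CR1`
#' inflates it by `G/(G-1)` for `G` clusters; `CR2` (default) applies the
#' symmetric cluster-level small-sample adjustment in the working-model
#' metric — residuals are whitened with the fitted marginal covariance, each
#' cluster is adjusted by `(I - H)_gg^{-1/2}`, and per-coefficient
#' Satterthwaite degrees of freedom are computed from the resulting influence
#' decomposition. Confidence intervals are t-based with those df (`G - 1` for
#' CR0/CR1).
#'
#' @param fit An `mlmv_fit` object.
#' @param estimator `"CR2"` (default), `"CR1"` or `"CR0"`.
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble of class `mlmv_robust`: `term`, `estimate`, `se_robust`,
#'   `df_robust`, `statistic`, `p.value`, `conf.low`, `conf.high`; attributes
#'   `estimator`, `cluster` (`"study"`) and `n_clusters`.
#' @export
robust_vcov <- function(fit, estimator = c("CR2", "CR1", "CR0"),
                        conf.level = 0.95) {
  stopifnot(inherits(fit, "mlmv_fit"))
  estimator <- match.arg(estimator)
  G <- fit$n_studies
  if (G < 2) stop("cluster-robust inference needs at least 2 studies",
                  call. = FALSE)
  X <- fit$X
  p <- ncol(X)
  beta <- fit$beta
  resid <- fit$y - as.vector(X %*% beta)

  # whiten per study with the fitted marginal covariance
  Xt <- vector("list", G)
  et <- vector("list", G)
  for (k in seq_len(G)) {
    st <- fit$studies[[k]]
    L <- chol(fit$M_blocks[[k]])
    Xt[[k]] <- backsolve(L, X[st$rows, , drop = FALSE], transpose = TRUE)
    et[[k]] <- backsolve(L, resid[st$rows], transpose = TRUE)
  }
  A <- Reduce(`+`, lapply(Xt, crossprod))
  B <- chol2inv(chol(A)) # bread: (X' M^-1 X)^-1

  Adj <- vector("list", G)
  fellback <- FALSE
  for (k in seq_len(G)) {
    if (estimator != "CR2") next
    Hgg <- Xt[[k]] %*% B %*% t(Xt[[k]])
    IH <- diag(nrow(Hgg)) - Hgg
    IH <- (IH + t(IH)) / 2
    e <- eigen(IH, symmetric = TRUE)
    if (min(e$values) < 1e-12) { fellback <- TRUE; next }
    Adj[[k]] <- e$vectors %*% (1 / sqrt(e$values) * t(e$vectors))
  }
  if (estimator == "CR2" && fellback) {
    warning("CR2 adjustment matrix singular for at least one cluster; ",
            "falling back to CR1", call. = FALSE)
    estimator <- "CR1"
    Adj <- vector("list", G)
  }

  meat <- matrix(0, p, p)
  scores <- vector("list", G) # adjusted X_g' A_g e_g, for Satterthwaite
  for (k in seq_len(G)) {
    Ae <- if (is.null(Adj[[k]])) et[[k]] else Adj[[k]] %*% et[[k]]
    AX <- if (is.null(Adj[[k]])) Xt[[k]] else Adj[[k]] %*% Xt[[k]]
    sk <- crossprod(AX, Ae) # p x 1
    scores[[k]] <- list(AX = AX, Xt = Xt[[k]])
    meat <- meat + tcrossprod(sk)
  }
  if (estimator == "CR1") meat <- meat * G / (G - 1)
  Vr <- B %*% meat %*% B
  Vr <- (Vr + t(Vr)) / 2
  se <- sqrt(pmax(diag(Vr), 0))

  df <- rep(G - 1, p)
  if (estimator == "CR2") {
    # Satterthwaite df per coefficient from the influence decomposition:
    # under the working model, V(c'beta) = sum_g (b_g' eps)^2 with
    # b_g' = u_g' (I - H)_{g,.},  u_g = A_g X~_g B c.
    for (j in seq_len(p)) {
      cvec <- numeric(p); cvec[j] <- 1
      u <- lapply(seq_len(G), function(k) scores[[k]]$AX %*% B %*% cvec)
      w <- lapply(seq_len(G), function(k) crossprod(scores[[k]]$Xt, u[[k]]))
      FF <- matrix(0, G, G)
      for (g in seq_len(G)) {
        for (h in seq_len(g)) {
          val <- -crossprod(w[[g]], B %*% w[[h]])[1, 1]
          if (g == h) val <- val + sum(u[[g]]^2)
          FF[g, h] <- FF[h, g] <- val
        }
      }
      tr <- sum(diag(FF))
      df[j] <- if (tr > 0) tr^2 / sum(FF^2) else NA_real_
    }
  }

  tcrit <- stats::qt(1 - (1 - conf.level) / 2, df)
  tstat <- beta / se
  out <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se_robust = unname(se),
    df_robust = unname(df), statistic = unname(tstat),
    p.value = 2 * stats::pt(-abs(unname(tstat)), unname(df)),
    conf.low = unname(beta - tcrit * se),
    conf.high = unname(beta + tcrit * se)
  )
  attr(out, "vcov") <- Vr
  attr(out, "estimator") <- estimator
  attr(out, "cluster") <- "study"
  attr(out, "n_clusters") <- G
  class(out) <- c("mlmv_robust", class(out))
  out
}

#' Likelihood-ratio test between nested working models
#'
#' Compares a restricted variance structure against a fuller one on the same
#' data. Under REML both fits must share the identical fixed-effect design
#' (enforced); the degrees of freedom equal the difference in free variance
#' parameters. The naive chi-square reference is reported; when either fit has
#' variance components at the zero boundary a caveat is attached (the
#' boundary-mixture null is not implemented).
#'
#' @param fit_restricted,fit_full `mlmv_fit` objects, restricted structure
#'   nested in the full structure (e.g. Model 2 vs Model 1).
#' @return One-row tibble: `chi2`, `df`, `p.value`, `boundary_caveat`.
#' @export
lrt <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "mlmv_fit"), inherits(fit_full, "mlmv_fit"))
  if (!identical(fit_restricted$method, fit_full$method)) {
    stop("fits use different estimation methods", call. = FALSE)
  }
  if (fit_restricted$method == "REML" &&
      !isTRUE(all.equal(fit_restricted$X, fit_full$X))) {
    stop("REML likelihood-ratio tests require identical fixed-effect designs",
         call. = FALSE)
  }
  mr <- fit_restricted$model; mf <- fit_full$model
  if (!(.nests_in(mr$within, mf$within) && .nests_in(mr$between, mf$between) &&
        mr$rho == mf$rho && mr$phi == mf$phi && mr$scale == mf$scale)) {
    stop("models are not nested: restricted (within ", mr$within, ", between ",
         mr$between, ") does not nest in full (within ", mf$within,
         ", between ", mf$between, ")", call. = FALSE)
  }
  df <- fit_full$n_varpar - fit_restricted$n_varpar
  if (df < 0) stop("restricted model has more variance parameters than the full model",
                   call. = FALSE)
  chi2 <- max(0, 2 * (fit_full$loglik - fit_restricted$loglik))
  p <- if (df == 0) {
    if (chi2 <= 1e-8) 1 else NA_real_
  } else stats::pchisq(chi2, df, lower.tail = FALSE)
  caveat <- any(fit_restricted$boundary) || any(fit_full$boundary)
  if (caveat) {
    message("variance component(s) at the zero boundary: the chi-square ",
            "reference is conservative")
  }
  tibble::tibble(chi2 = chi2, df = df, p.value = p, boundary_caveat = caveat)
}

#' Information-criterion comparison of fitted models
#'
#' @param ... `mlmv_fit` objects (or a single list of them), fitted to the
#'   same data with the same method and fixed design.
#' @return Tibble with one row per model: log-likelihood, deviance, AIC, BIC,
#'   AICc, per-criterion ranks and a `best` flag (minimum BIC, the default
#'   selection criterion).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "mlmv_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "mlmv_fit")))
  methods <- vapply(fits, function(f) f$method, character(1))
  if (length(unique(methods)) > 1) {
    stop("cannot compare fits with mixed estimation methods", call. = FALSE)
  }
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab <- dplyr::mutate(
    tab,
    rank_AIC = rank(.data$AIC, ties.method = "min"),
    rank_BIC = rank(.data$BIC, ties.method = "min"),
    rank_AICc = rank(.data$AICc, ties.method = "min"),
    best = .data$BIC == min(.data$BIC)
  )
  tab
}
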