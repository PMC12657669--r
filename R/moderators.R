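#' Specify a cell-by-moderator meta-regression design
#'
#' Two parameterizations are offered for categorical moderators. The
#' `interaction` form keeps one column per cell (serving as the intercepts:
#' the pooled correlation at the reference level) and adds cell-by-level
#' columns for every non-reference level, so each interaction coefficient is
#' that cell's moderator effect. The `subgroup` form crosses cells with all
#' levels, giving one pooled estimate per (cell, level) pair with no
#' between-group test. Continuous moderators always use the interaction form:
#' cell intercepts plus per-cell slopes. Both forms suppress the global
#' intercept. Rows with a missing moderator value are dropped from the
#' moderated fit (with a message).
#'
#' @param moderator Column name in the dataset.
#' @param kind `"auto"` (default; factor/character/logical are categorical),
#'   `"categorical"` or `"continuous"`.
#' @param parameterization `"interaction"` (default) or `"subgroup"`
#'   (categorical only).
#' @param ref Reference level for categorical moderators; default is the
#'   first level in sorted order.
#' @param center Center a continuous moderator at its mean before crossing
#'   (default `FALSE`; the moderator scale is taken as given, never rescaled
#'   silently).
#' @return Object of class `moderator_spec`.
#' @export
moderator_spec <- function(moderator,
                           kind = c("auto", "categorical", "continuous"),
                           parameterization = c("interaction", "subgroup"),
                           ref = NULL, center = FALSE) {
  structure(list(moderator = moderator, kind = match.arg(kind),
                 parameterization = match.arg(parameterization),
                 ref = ref, center = center),
            class = "moderator_spec")
}

#' Fit a moderated (mixed-effects) meta-regression
#'
#' Convenience wrapper: [mlmv_fit()] with the fixed design extended by
#' `spec`. The random-effect structure stays that of `model`.
#'
#' @inheritParams mlmv_fit
#' @param spec A [moderator_spec()].
#' @return An `mlmv_fit`.
#' @export
fit_moderated <- function(data, spec, model = working_model(2), vmat = NULL,
                          method = c("REML", "ML"), control = list()) {
  stopifnot(inherits(spec, "moderator_spec"))
  mlmv_fit(data, model = model, vmat = vmat, moderator = spec,
           method = match.arg(method), control = control)
}

#' Per-level, per-cell variance explained by a moderator
#'
#' Compares the heterogeneity variance estimates of a moderated fit against
#' the unmoderated fit with the same variance structure:
#' `R^2 = max(0, (sigma2_null - sigma2_mod) / sigma2_null)`, computed per cell
#' at levels with per-cell variances (HCS/DIAG) and once at levels with a
#' shared variance (CS/ID). Negative raw values — routine sampling
#' fluctuation in meta-analytic R^2 — are truncated at zero and flagged.
#'
#' @param fit_null Unmoderated `mlmv_fit` (cells-only fixed design).
#' @param fit_mod Moderated `mlmv_fit` sharing data, method and variance
#'   structures.
#' @return Tibble: `level` (`"within"`/`"between"`), `cell` (`NA` for shared
#'   variances), `r2`, `truncated`. `r2` is `NA` where the null variance is 0.
#' @export
variance_explained <- function(fit_null, fit_mod) {
  stopifnot(inherits(fit_null, "mlmv_fit"), inherits(fit_mod, "mlmv_fit"))
  mn <- fit_null$model; mm <- fit_mod$model
  if (!identical(mn$within, mm$within) || !identical(mn$between, mm$between) ||
      mn$rho != mm$rho || mn$phi != mm$phi || mn$scale != mm$scale ||
      !identical(fit_null$method, fit_mod$method)) {
    stop("fits must share variance structures, fixed correlations, scale and method",
         call. = FALSE)
  }
  if (fit_mod$p_fixed <= fit_null$p_fixed) {
    stop("the moderated fit must extend the null fit's fixed design",
         call. = FALSE)
  }
  one_level <- function(level, v_null, v_mod) {
    raw <- (v_null - v_mod) / v_null
    r2 <- pmax(0, raw)
    r2[v_null == 0] <- NA_real_
    tibble::tibble(level = level,
                   cell = if (length(v_null) > 1) names(v_null) else NA_character_,
                   r2 = unname(r2),
                   truncated = unname(is.finite(raw) & raw < 0))
  }
  dplyr::bind_rows(
    one_level("within", fit_null$tau2, fit_mod$tau2),
    one_level("between", fit_null$gamma2, fit_mod$gamma2)
  )
}

#' Linear contrasts on fitted coefficients
#'
#' Tests `L beta = 0` rows at a time with model-based or cluster-robust
#' covariance, e.g. between-group differences under the subgroup
#' parameterization.
#'
#' @param fit An `mlmv_fit`.
#' @param L Contrast matrix (rows are contrasts) or a single named numeric
#'   vector over coefficients.
#' @param robust Use [robust_vcov()] CR2 covariance instead of the
#'   model-based one.
#' @return Tibble: `contrast`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
contrast_test <- function(fit, L, robust = FALSE) {
  stopifnot(inherits(fit, "mlmv_fit"))
  if (is.null(dim(L))) L <- matrix(L, nrow = 1, dimnames = list("contrast", names(L)))
  if (!is.null(colnames(L))) {
    full <- matrix(0, nrow(L), length(fit$beta),
                   dimnames = list(rownames(L), names(fit$beta)))
    full[, colnames(L)] <- L
    L <- full
  }
  V <- if (robust) attr(robust_vcov(fit), "vcov") else fit$vcov_beta
  est <- as.vector(L %*% fit$beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  z <- est / se
  tibble::tibble(contrast = rownames(L) %||% paste0("L", seq_along(est)),
                 estimate = est, std.error = se, statistic = z,
                 p.value = 2 * stats::pnorm(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- design construction ---------------------------------------------------

.moderator_missing <- function(data, spec) {
  if (!spec$moderator %in% names(data)) {
    stop("moderator column '", spec$moderator, "' not found", call. = FALSE)
  }
  data$es_id[is.na(data[[spec$moderator]])]
}

.extend_design_moderator <- function(base, data, vec, cells_used, spec) {
  x <- data[[spec$moderator]]
  kind <- spec$kind
  if (kind == "auto") {
    # numeric with more than two distinct values is a continuous moderator;
    # 0/1 dummies and labels are categorical
    kind <- if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2) {
      "continuous"
    } else "categorical"
  }
  C <- length(cells_used)
  if (kind == "continuous") {
    x <- as.numeric(x)
    if (stats::sd(x) == 0) {
      stop("moderator '", spec$moderator, "' is constant", call. = FALSE)
    }
    if (spec$center) x <- x - mean(x)
    inter <- base * x
    colnames(inter) <- paste0(cells_used, ":", spec$moderator)
    X <- cbind(base, inter)
    info <- list(kind = "continuous", moderator = spec$moderator,
                 parameterization = "interaction")
  } else {
    x <- as.character(x)
    levels <- sort(unique(x))
    if (length(levels) < 2) {
      stop("moderator '", spec$moderator, "' is constant", call. = FALSE)
    }
    ref <- spec$ref %||% levels[1]
    if (!ref %in% levels) stop("reference level '", ref, "' not present",
                               call. = FALSE)
    if (spec$parameterization == "interaction") {
      others <- setdiff(levels, ref)
      cols <- lapply(others, function(lv) {
        m <- base * (x == lv)
        colnames(m) <- paste0(cells_used, ":", spec$moderator, lv)
        m
      })
      X <- do.call(cbind, c(list(base), cols))
    } else {
      cols <- lapply(levels, function(lv) {
        m <- base * (x == lv)
        colnames(m) <- paste0(cells_used, ":", spec$moderator, lv)
        m
      })
      X <- do.call(cbind, cols)
    }
    empty <- colSums(X != 0) == 0
    if (any(empty)) {
      stop("empty cell-by-level combination(s): ",
           paste(colnames(X)[empty], collapse = ", "), call. = FALSE)
    }
    info <- list(kind = "categorical", moderator = spec$moderator,
                 parameterization = spec$parameterization, ref = ref,
                 levels = levels)
  }
  list(X = X, cells_used = cells_used, info = info)
}
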