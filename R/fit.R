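#' Fit a multilevel multivariate random-effects meta-analysis
#'
#' Pools correlation matrices across studies under a [working_model()]: fixed
#' effects are one pooled coefficient per cell (optionally crossed with a
#' moderator), Level-2 random effects are per-sample deviations with
#' covariance `T` over cells, Level-3 random effects are per-study deviations
#' with covariance `Gamma`, and Level-1 sampling error has the known
#' block-diagonal covariance `V`. Estimation is restricted (REML, default) or
#' full maximum likelihood; variance parameters are optimized on the log scale
#' with a fixed set of starting values, so fitting is deterministic.
#'
#' Cells missing from a sample's matrix are simply absent from the likelihood
#' (no imputation). With no study contributing two or more samples, the
#' within- and between-study variances are identified only in sum; a warning
#' is issued and estimates should be read accordingly.
#'
#' @param data A `cor_data` object.
#' @param model A [working_model()]; defaults to Model 1 (per-cell variances
#'   at both levels, independent random effects).
#' @param vmat A `cor_vmat` from [build_vmat()], matching `model`'s scale.
#'   Built automatically (dependent mode) when `NULL`.
#' @param moderator Optional [moderator_spec()] extending the fixed design
#'   with cell-by-moderator terms.
#' @param method `"REML"` (default) or `"ML"`.
#' @param control List of optimizer settings passed to [stats::nlminb()]
#'   (defaults: `iter.max = 500`, `rel.tol = 1e-10`).
#' @return An object of class `mlmv_fit`; use [tidy()][generics::tidy] for the
#'   coefficient table, [glance()][generics::glance] for fit statistics,
#'   `$tau2` / `$gamma2` for heterogeneity estimates, [robust_vcov()] for
#'   cluster-robust inference and [autoplot()][ggplot2::autoplot] for a forest
#'   plot.
#' @examples
#' sim <- simulate_cor_data(sim_config(n_studies = 15), seed = 1)
#' fit <- mlmv_fit(sim$data, working_model(4))
#' glance(fit)
#' tidy(fit)
#' @export
mlmv_fit <- function(data, model = working_model(1), vmat = NULL,
                     moderator = NULL, method = c("REML", "ML"),
                     control = list()) {
  stopifnot(inherits(data, "cor_data"), inherits(model, "working_model"))
  method <- match.arg(method)

  if (!is.null(moderator)) {
    dropped <- .moderator_missing(data, moderator)
    if (length(dropped) > 0) {
      message(length(dropped), " row(s) with missing '", moderator$moderator,
              "' dropped from the moderator fit")
      data <- .subset_cor_data(data, setdiff(data$es_id, dropped))
      vmat <- NULL # alignment changed; rebuild below
    }
  }
  if (is.null(vmat)) {
    vmat <- build_vmat(data, mode = "dependent", scale = model$scale)
  }
  if (!identical(vmat$scale, model$scale)) {
    stop("sampling covariance scale ('", vmat$scale,
         "') does not match the model scale ('", model$scale, "')",
         call. = FALSE)
  }
  vec <- cor_vectorize(data)
  if (!identical(vmat$index$es_id, vec$index$es_id)) {
    stop("sampling covariance matrix is not aligned with the dataset",
         call. = FALSE)
  }
  y <- if (model$scale == "fisher_z") r_to_z(vec$y) else vec$y

  design <- .build_fixed_design(data, moderator)
  X <- design$X
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p)]]
    stop("fixed design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  N <- length(y)
  if (N < p + 1) stop("need at least p + 1 rows to fit", call. = FALSE)

  cells_used <- design$cells_used
  C <- length(cells_used)
  studies <- .prepare_studies(vec$index, vmat, cells_used)
  for (k in seq_along(studies)) {
    studies[[k]]$X <- X[studies[[k]]$rows, , drop = FALSE]
    studies[[k]]$y <- y[studies[[k]]$rows]
    Zc <- outer(studies[[k]]$cell_pos, seq_len(C), `==`) * 1
    studies[[k]]$Zc <- Zc
    for (j in seq_along(studies[[k]]$samples)) {
      loc <- studies[[k]]$samples[[j]]$loc
      studies[[k]]$samples[[j]]$Zc <- Zc[loc, , drop = FALSE]
    }
  }

  multi <- !any(vapply(studies, function(s) length(s$samples) > 1, logical(1)))
  if (multi) {
    warning("no study contributes 2+ samples: within- and between-study ",
            "variances are identified only in sum", call. = FALSE)
  }

  q_w <- .n_varpar(model$within, C)
  q_b <- .n_varpar(model$between, C)
  q <- q_w + q_b

  obj <- function(theta) {
    .neg_ll(theta, y, X, studies, model, q_w, q_b, C, method, p, N)
  }
  gr <- function(theta) {
    .neg_ll_grad(theta, y, X, studies, model, q_w, q_b, C, method, p, N)
  }

  # deterministic two-stage multistart: short probe runs from 4 fixed starting
  # points, then a full optimization from the best probe
  starts <- expand.grid(w = log(c(1e-4, 1e-2)), b = log(c(1e-4, 1e-2)))
  ctrl <- utils::modifyList(list(iter.max = 500L, eval.max = 4000L,
                                 rel.tol = 1e-10), control)
  probe_ctrl <- utils::modifyList(ctrl, list(iter.max = 10L, eval.max = 200L))
  best <- NULL
  n_iter <- 0L
  probes <- list()
  for (s in seq_len(nrow(starts))) {
    th0 <- c(rep(starts$w[s], q_w), rep(starts$b[s], q_b))
    opt <- tryCatch(
      stats::nlminb(th0, obj, gradient = gr, lower = rep(-30, q),
                    upper = rep(3, q), control = probe_ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    n_iter <- n_iter + opt$iterations
    probes[[length(probes) + 1]] <- opt
  }
  if (length(probes) == 0) {
    stop("all optimizer starts failed; the marginal covariance could not be ",
         "evaluated", call. = FALSE)
  }
  # polish the two most promising probes: with many variance parameters a
  # single short probe can pick a start that converges marginally short of
  # the optimum
  ord <- order(vapply(probes, function(o) o$objective, numeric(1)))
  for (i in utils::head(ord, 2)) {
    final <- tryCatch(
      stats::nlminb(probes[[i]]$par, obj, gradient = gr, lower = rep(-30, q),
                    upper = rep(3, q), control = ctrl),
      error = function(e) NULL)
    if (is.null(final)) next
    n_iter <- n_iter + final$iterations
    if (is.null(best) || final$objective < best$objective - 1e-10) {
      best <- final
    }
  }
  if (is.null(best)) best <- probes[[ord[1]]]
  theta <- best$par
  converged <- is.finite(best$objective) &&
    (best$convergence == 0 || .stationary(obj, theta, best$objective))

  tau2 <- exp(theta[seq_len(q_w)])
  gamma2 <- exp(theta[q_w + seq_len(q_b)])
  names(tau2) <- if (q_w == C) cells_used else "tau2"
  names(gamma2) <- if (q_b == C) cells_used else "gamma2"
  boundary <- c(theta[seq_len(q_w)], theta[q_w + seq_len(q_b)]) < -25
  names(boundary) <- c(paste0("tau2.", names(tau2)),
                       paste0("gamma2.", names(gamma2)))

  fin <- .gls_pieces(theta, y, X, studies, model, q_w, q_b, C)
  if (is.null(fin)) {
    stop("marginal covariance not positive definite at the optimum",
         call. = FALSE)
  }
  beta <- fin$beta
  vcov_beta <- fin$vcov
  loglik <- -best$objective
  dev <- -2 * loglik

  q_params <- if (method == "REML") q else p + q
  m <- if (method == "REML") N - p else N
  aic <- dev + 2 * q_params
  bic <- dev + log(m) * q_params
  aicc <- if (m - q_params - 1 > 0) {
    aic + 2 * q_params * (q_params + 1) / (m - q_params - 1)
  } else Inf

  qe <- .qe_statistic(y, X, studies)

  structure(list(
    beta = beta, vcov_beta = vcov_beta,
    tau2 = tau2, gamma2 = gamma2,
    model = model, method = method, moderator = moderator,
    loglik = loglik, deviance = dev, aic = aic, bic = bic, aicc = aicc,
    q_params = q_params, n_varpar = q, p_fixed = p, nobs = N,
    qe = qe$Q, qe_df = qe$df, qe_p = qe$p,
    converged = converged, n_iter = n_iter, boundary = boundary,
    cells = cells_used, y = y, X = X, index = vec$index,
    studies = studies, M_blocks = fin$M_blocks,
    n_samples = length(unique(vec$index$sample_id)),
    n_studies = length(studies),
    design_info = design$info
  ), class = "mlmv_fit")
}

# ---- internals -------------------------------------------------------------

# optimizer codes other than 0 can still sit at a genuine optimum (common with
# variance parameters pinned to the boundary); accept if the interior
# coordinates have a numerically flat central-difference gradient
.stationary <- function(obj, theta, f0, h = 1e-4, tol = 1e-3) {
  free <- which(theta > -25)
  if (length(free) == 0) return(TRUE)
  g <- vapply(free, function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (obj(tp) - obj(tm)) / (2 * h)
  }, numeric(1))
  max(abs(g)) < tol
}

# cell-indicator design (plus moderator terms when spec given)
.build_fixed_design <- function(data, moderator = NULL) {
  vec <- cor_vectorize(data)
  cells_used <- attr(data, "cells")$label[
    sort(unique(vec$index$cell_idx))]
  base <- outer(vec$index$cell, cells_used, `==`) * 1
  colnames(base) <- cells_used
  if (is.null(moderator)) {
    return(list(X = base, cells_used = cells_used,
                info = list(kind = "cells")))
  }
  .extend_design_moderator(base, data, vec, cells_used, moderator)
}

# per-study precomputation: rows, local cell indices, per-sample V blocks
.prepare_studies <- function(index, vmat, cells_used) {
  lapply(split(seq_len(nrow(index)), factor(index$study_id,
                                            levels = unique(index$study_id))),
         function(rows) {
           cell_pos <- match(index$cell[rows], cells_used)
           samples <- lapply(split(seq_along(rows), factor(
             index$sample_id[rows], levels = unique(index$sample_id[rows]))),
             function(loc) {
               sid <- index$sample_id[rows[loc[1]]]
               list(sid = sid, loc = loc, V = vmat$blocks[[sid]])
             })
           list(rows = rows, cell_pos = cell_pos, samples = samples)
         })
}

# marginal covariance of one study block
.study_M <- function(st, Tm, Gm) {
  m <- length(st$rows)
  M <- Gm[st$cell_pos, st$cell_pos, drop = FALSE]
  for (sm in st$samples) {
    loc <- sm$loc
    M[loc, loc] <- M[loc, loc] + sm$V +
      Tm[st$cell_pos[loc], st$cell_pos[loc], drop = FALSE]
  }
  (M + t(M)) / 2
}

.theta_cov <- function(theta, model, q_w, q_b, C) {
  tau2 <- exp(theta[seq_len(q_w)])
  gamma2 <- exp(theta[q_w + seq_len(q_b)])
  list(Tm = .re_cov(tau2, model$rho, C), Gm = .re_cov(gamma2, model$phi, C))
}

# negative (restricted) log-likelihood; large penalty on non-PD blocks so the
# optimizer backs away instead of crashing
.neg_ll <- function(theta, y, X, studies, model, q_w, q_b, C, method, p, N) {
  cov <- .theta_cov(theta, model, q_w, q_b, C)
  logdet <- 0
  A <- matrix(0, p, p)
  b <- numeric(p)
  yy <- 0
  for (st in studies) {
    M <- .study_M(st, cov$Tm, cov$Gm)
    L <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(L)) return(1e10 + sum(theta^2))
    logdet <- logdet + 2 * sum(log(diag(L)))
    Zx <- backsolve(L, st$X, transpose = TRUE)
    zy <- backsolve(L, st$y, transpose = TRUE)
    A <- A + crossprod(Zx)
    b <- b + crossprod(Zx, zy)[, 1]
    yy <- yy + sum(zy^2)
  }
  Ra <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ra)) return(1e10 + sum(theta^2))
  beta <- backsolve(Ra, backsolve(Ra, b, transpose = TRUE))
  quad <- yy - sum(b * beta)
  if (quad < 0) quad <- 0
  if (method == "REML") {
    0.5 * ((N - p) * log(2 * pi) + logdet + 2 * sum(log(diag(Ra))) + quad)
  } else {
    0.5 * (N * log(2 * pi) + logdet + quad)
  }
}

# analytic gradient of the negative (restricted) log-likelihood on the
# log-variance scale. M is built from per-cell structure matrices, so each
# derivative d M / d theta_i places a small C x C matrix (dT or dGamma) into
# the same-sample / same-study positions:
#   REML: d(-ll)/dtheta_i = 0.5 * [tr(M^-1 Mdot) - tr(A^-1 X'M^-1 Mdot M^-1 X)
#                                   - r' M^-1 Mdot M^-1 r],  r = y - X betahat
#   ML:   drop the A^-1 trace term.
.neg_ll_grad <- function(theta, y, X, studies, model, q_w, q_b, C, method, p, N) {
  cov <- .theta_cov(theta, model, q_w, q_b, C)
  tau2 <- exp(theta[seq_len(q_w)])
  gamma2 <- exp(theta[q_w + seq_len(q_b)])
  q <- q_w + q_b

  # pass 1: factor blocks and assemble the GLS solution
  pieces <- vector("list", length(studies))
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (k in seq_along(studies)) {
    st <- studies[[k]]
    M <- .study_M(st, cov$Tm, cov$Gm)
    L <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(L)) return(2 * theta) # gradient of the non-PD penalty
    Minv <- chol2inv(L)
    G <- Minv %*% st$X
    A <- A + crossprod(st$X, G)
    b <- b + crossprod(G, st$y)[, 1]
    pieces[[k]] <- list(Minv = Minv, G = G)
  }
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(Ainv)) return(2 * theta)
  beta <- (Ainv %*% b)[, 1]

  # the log-scale derivative of an HCS block w.r.t. cell c decomposes as
  #   0.5 rho s_c (e_c w' + w e_c') + (1 - rho) v_c e_c e_c',  w = sqrt(v),
  # and a shared (CS) variance scales its whole block linearly. Mapped to
  # observation rows these are per-cell indicator and rank-one pieces, so each
  # study's contribution to every component reduces to cell-grouped sums of
  # Heff = M^-1 - M^-1 X A^-1 X' M^-1 (REML; M^-1 for ML) and u = M^-1 r.
  tau2_full <- if (q_w == C) tau2 else rep(tau2, C)
  gamma2_full <- if (q_b == C) gamma2 else rep(gamma2, C)
  grad <- numeric(q)
  for (k in seq_along(studies)) {
    st <- studies[[k]]
    Minv <- pieces[[k]]$Minv
    G <- pieces[[k]]$G
    u <- (Minv %*% (st$y - st$X %*% beta))[, 1]
    Heff <- if (method == "REML") Minv - G %*% Ainv %*% t(G) else Minv
    gb <- .level_grad(Heff, u, st$Zc, gamma2_full, model$phi, q_b)
    gw <- numeric(q_w)
    for (sm in st$samples) {
      loc <- sm$loc
      gw <- gw + .level_grad(Heff[loc, loc, drop = FALSE], u[loc], sm$Zc,
                             tau2_full, model$rho, q_w)
    }
    grad <- grad + 0.5 * c(gw, gb)
  }
  grad
}

# per-level gradient pieces: tr(Heff Mdot_i) - u' Mdot_i u for every
# log-variance parameter of one level; Zc is the rows-by-cells 0/1 indicator
.level_grad <- function(H, u, Zc, v, rho, qlev) {
  s <- sqrt(v)
  HZ <- H %*% Zc
  ru <- crossprod(Zc, u)[, 1]
  Sd <- colSums(Zc * HZ)              # z_c' H z_c per cell
  if (qlev == length(v)) {
    w_row <- (Zc %*% s)[, 1]
    a1 <- crossprod(Zc, HZ %*% s)[, 1]
    wu <- sum(w_row * u)
    g_tr <- rho * s * a1 + (1 - rho) * v * Sd
    g_u <- rho * s * ru * wu + (1 - rho) * v * ru^2
    g_tr - g_u
  } else {
    vs <- v[1]
    g_tr <- vs * ((1 - rho) * sum(Sd) + rho * sum(H))
    g_u <- vs * ((1 - rho) * sum(ru^2) + rho * sum(u)^2)
    g_tr - g_u
  }
}

# GLS solution and per-study marginal covariances at given theta
.gls_pieces <- function(theta, y, X, studies, model, q_w, q_b, C) {
  cov <- .theta_cov(theta, model, q_w, q_b, C)
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  M_blocks <- vector("list", length(studies))
  names(M_blocks) <- names(studies)
  for (k in seq_along(studies)) {
    st <- studies[[k]]
    M <- .study_M(st, cov$Tm, cov$Gm)
    L <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    M_blocks[[k]] <- M
    Xs <- X[st$rows, , drop = FALSE]
    Zx <- backsolve(L, Xs, transpose = TRUE)
    zy <- backsolve(L, y[st$rows], transpose = TRUE)
    A <- A + crossprod(Zx)
    b <- b + crossprod(Zx, zy)[, 1]
  }
  Ainv <- chol2inv(chol(A))
  beta <- (Ainv %*% b)[, 1]
  names(beta) <- colnames(X)
  dimnames(Ainv) <- list(colnames(X), colnames(X))
  list(beta = beta, vcov = Ainv, M_blocks = M_blocks)
}

# residual heterogeneity Q from the fixed-effects GLS fit with weights V^-1
.qe_statistic <- function(y, X, studies) {
  p <- ncol(X)
  N <- length(y)
  A <- matrix(0, p, p)
  b <- numeric(p)
  yy <- 0
  for (st in studies) {
    for (sm in st$samples) {
      rows <- st$rows[sm$loc]
      L <- tryCatch(chol(sm$V), error = function(e) {
        stop("singular sampling covariance block for sample '", sm$sid, "'",
             call. = FALSE)
      })
      Zx <- backsolve(L, X[rows, , drop = FALSE], transpose = TRUE)
      zy <- backsolve(L, y[rows], transpose = TRUE)
      A <- A + crossprod(Zx)
      b <- b + crossprod(Zx, zy)[, 1]
      yy <- yy + sum(zy^2)
    }
  }
  beta <- solve(A, b)
  Q <- max(0, yy - sum(b * beta))
  df <- N - p
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

# subset rows of a cor_data by es_id, preserving rosters and order
.subset_cor_data <- function(data, keep_es) {
  out <- tibble::as_tibble(data)[data$es_id %in% keep_es, , drop = FALSE]
  structure(out, class = class(data), variables = attr(data, "variables"),
            cells = attr(data, "cells"), moderators = attr(data, "moderators"))
}
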