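#' Configuration for the correlation-matrix meta-analysis generator
#'
#' Describes the generative process the model assumes: a population
#' correlation vector over cells, per-study (Level-3) deviations with
#' covariance `Gamma(gamma2, phi_b)`, per-sample (Level-2) deviations with
#' covariance `T(tau2, rho_w)`, and Level-1 sampling error — either by drawing
#' raw multivariate-normal observations and computing Pearson correlations
#' (`mode = "exact"`) or by drawing the observed vector from the large-sample
#' normal approximation at the latent values (`mode = "asymptotic"`).
#'
#' The defaults mirror a typical item-correlation meta-analysis of the kind
#' the model targets: 5 variables (10 cells), 62 studies, 1–4 samples per
#' study with mean 1.4, right-skewed sample sizes with median near 327 (range
#' clamped to [99, 12706]), population correlations near 0.4, and small
#' heterogeneity variances of the order 10^-3.
#'
#' @param n_variables Number of variables I (cells = I(I-1)/2).
#' @param mu Population correlation: scalar (constant off-diagonal), or an
#'   I x I positive-definite correlation matrix, or a per-cell vector in
#'   roster order.
#' @param tau2 Within-study heterogeneity variance: scalar or per-cell vector.
#' @param gamma2 Between-study heterogeneity variance: scalar or per-cell
#'   vector.
#' @param rho_w,phi_b Fixed correlations among Level-2 / Level-3 random
#'   effects, in [0, 1].
#' @param n_studies Number of primary studies K.
#' @param samples_per_study Either a single integer or a probability vector
#'   over counts 1, 2, 3, ... (default `c(.70, .22, .06, .02)`, mean 1.4).
#' @param n_per_sample Either a single integer or a list
#'   `list(meanlog=, sdlog=, min=, max=)` for a clamped lognormal.
#' @param missing_rate Per-cell probability that a sample's correlation is
#'   unreported.
#' @param moderator Optional list describing one moderator:
#'   `list(name=, kind="binary"|"continuous", level="sample"|"study",
#'   prob=` (binary) `or mean=, sd=` (continuous)`, slope=)` with `slope` a
#'   scalar or per-cell vector of latent mean shifts per moderator unit.
#' @param mode `"exact"` (default) or `"asymptotic"`.
#' @param v_at For asymptotic mode: evaluate the Level-1 covariance at each
#'   sample's `"latent"` correlations (default; realistic emulation — the
#'   sampling covariance then co-varies with the random effects) or at the
#'   `"population"` values (strictly model-faithful: V is a known, exogenous
#'   constant given n, the assumption the estimator actually makes). Ignored
#'   in exact mode, where raw-data sampling fixes the coupling.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_variables = 5, mu = 0.4, tau2 = 0.005,
                       gamma2 = 0.003, rho_w = 0, phi_b = 0,
                       n_studies = 62,
                       samples_per_study = c(0.70, 0.22, 0.06, 0.02),
                       n_per_sample = list(meanlog = log(327), sdlog = 1,
                                           min = 99, max = 12706),
                       missing_rate = 0, moderator = NULL,
                       mode = c("exact", "asymptotic"),
                       v_at = c("latent", "population")) {
  mode <- match.arg(mode)
  v_at <- match.arg(v_at)
  I <- n_variables
  C <- I * (I - 1) / 2
  vars <- paste0("V", seq_len(I))
  roster <- cell_roster(vars)
  if (is.matrix(mu)) {
    stopifnot(nrow(mu) == I, ncol(mu) == I)
    mu_vec <- mu[cbind(match(roster$var_a, vars), match(roster$var_b, vars))]
  } else if (length(mu) == C) {
    mu_vec <- as.numeric(mu)
  } else if (length(mu) == 1) {
    mu_vec <- rep(mu, C)
  } else stop("mu must be scalar, per-cell vector, or I x I matrix",
              call. = FALSE)
  Rmu <- diag(I)
  Rmu[cbind(match(roster$var_a, vars), match(roster$var_b, vars))] <- mu_vec
  Rmu[cbind(match(roster$var_b, vars), match(roster$var_a, vars))] <- mu_vec
  if (min(eigen(Rmu, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("population correlation matrix must be positive definite",
         call. = FALSE)
  }
  stopifnot(all(tau2 >= 0), all(gamma2 >= 0),
            length(tau2) %in% c(1L, C), length(gamma2) %in% c(1L, C),
            rho_w >= 0, rho_w <= 1, phi_b >= 0, phi_b <= 1,
            missing_rate >= 0, missing_rate < 1, n_studies >= 1)
  structure(list(
    n_variables = I, variables = vars, roster = roster, mu = mu_vec,
    mu_matrix = Rmu, tau2 = tau2, gamma2 = gamma2, rho_w = rho_w,
    phi_b = phi_b, n_studies = n_studies,
    samples_per_study = samples_per_study, n_per_sample = n_per_sample,
    missing_rate = missing_rate, moderator = moderator, mode = mode,
    v_at = v_at
  ), class = "sim_config")
}

#' Simulate a correlation-matrix meta-analytic dataset
#'
#' Draws study-level and sample-level random effects, forms each sample's
#' latent correlation vector (clamped to (-0.999, 0.999)), and produces
#' observed correlations either from raw multivariate-normal data (exact
#' mode; each latent matrix is repaired to the nearest valid correlation
#' matrix before drawing) or from the large-sample normal approximation.
#' Missingness and moderator-driven latent shifts are applied as configured.
#' Fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `data` (a `cor_data`) and `truth` (class `sim_truth`):
#'   the true pooled correlations, variance components, moderator slopes,
#'   per-sample latent vectors, clamp and repair rates, and the seed.
#' @export
simulate_cor_data <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  I <- config$n_variables
  C <- nrow(config$roster)
  vars <- config$variables
  roster <- config$roster
  Tm <- .re_cov(if (length(config$tau2) == 1) rep(config$tau2, C) else config$tau2,
                config$rho_w, C)
  Gm <- .re_cov(if (length(config$gamma2) == 1) rep(config$gamma2, C) else config$gamma2,
                config$phi_b, C)
  slopes <- NULL
  if (!is.null(config$moderator)) {
    s <- config$moderator$slope
    slopes <- if (length(s) == 1) rep(s, C) else as.numeric(s)
    stopifnot(length(slopes) == C)
  }

  n_clamped <- 0L
  n_latent <- 0L
  n_repaired <- 0L
  rows <- list()
  latents <- list()
  v_blocks <- list()
  pop_blocks <- list() # population-value Level-1 blocks cached by n
  sample_counter <- 0L
  for (k in seq_len(config$n_studies)) {
    J <- .draw_samples_per_study(config$samples_per_study)
    w_k <- .rmvn1(Gm)
    x_study <- .draw_moderator(config$moderator, level = "study")
    for (j in seq_len(J)) {
      sample_counter <- sample_counter + 1L
      sid <- sample_counter
      u_jk <- .rmvn1(Tm)
      x <- if (!is.null(config$moderator) &&
               identical(config$moderator$level %||% "sample", "study")) {
        x_study
      } else .draw_moderator(config$moderator, level = "sample")
      shift <- if (is.null(slopes)) 0 else slopes * x
      latent <- config$mu + shift + w_k + u_jk
      n_latent <- n_latent + C
      n_clamped <- n_clamped + sum(abs(latent) >= 0.999)
      latent <- pmin(pmax(latent, -0.999), 0.999)
      n_jk <- .draw_n(config$n_per_sample)

      V_true <- NULL
      if (config$mode == "exact") {
        Rl <- diag(I)
        Rl[cbind(match(roster$var_a, vars), match(roster$var_b, vars))] <- latent
        Rl[cbind(match(roster$var_b, vars), match(roster$var_a, vars))] <- latent
        ev <- eigen(Rl, symmetric = TRUE)
        if (min(ev$values) < 1e-6) {
          n_repaired <- n_repaired + 1L
          lam <- pmax(ev$values, 1e-6)
          Rl <- ev$vectors %*% (lam * t(ev$vectors))
          d <- 1 / sqrt(diag(Rl))
          Rl <- Rl * tcrossprod(d)
        }
        Lc <- chol(Rl)
        Zmat <- matrix(stats::rnorm(n_jk * I), n_jk, I) %*% Lc
        Robs <- stats::cor(Zmat)
        r_obs <- Robs[cbind(match(roster$var_a, vars),
                            match(roster$var_b, vars))]
        latent_eff <- Rl[cbind(match(roster$var_a, vars),
                               match(roster$var_b, vars))]
        V_true <- .olkin_block(latent_eff, roster, vars, n_jk)
      } else {
        Sig <- if (identical(config$v_at, "population")) {
          key <- as.character(n_jk)
          if (is.null(pop_blocks[[key]])) {
            pop_blocks[[key]] <- .olkin_block(config$mu, roster, vars, n_jk)
          }
          pop_blocks[[key]]
        } else {
          .olkin_block(latent, roster, vars, n_jk)
        }
        V_true <- Sig
        r_obs <- latent + .rmvn1(Sig)
        r_obs <- pmin(pmax(r_obs, -0.999), 0.999)
      }
      dimnames(V_true) <- list(roster$label, roster$label)

      keep <- stats::runif(C) >= config$missing_rate
      if (!any(keep)) next
      v_blocks[[as.character(sid)]] <- V_true[keep, keep, drop = FALSE]
      rows[[sid]] <- tibble::tibble(
        StudyID = k, SampleID = sid,
        Var1 = roster$var_a[keep], Var2 = roster$var_b[keep],
        Correlation = r_obs[keep], N = n_jk,
        ..mod = if (is.null(config$moderator)) NA_real_ else x
      )
      latents[[sid]] <- tibble::tibble(study_id = k, sample_id = sid,
                                       cell = roster$label, latent = latent)
    }
  }
  df <- dplyr::bind_rows(rows)
  if (is.null(config$moderator)) {
    df$..mod <- NULL
  } else {
    names(df)[names(df) == "..mod"] <- config$moderator$name
  }
  clamp_rate <- n_clamped / max(1L, n_latent)
  if (clamp_rate > 0.05) {
    warning(sprintf("%.1f%% of latent correlations were clamped; heterogeneity may dominate the admissible range",
                    100 * clamp_rate), call. = FALSE)
  }
  data <- cor_data(df, variable_order = vars)
  truth <- structure(list(
    mu = stats::setNames(config$mu, roster$label),
    tau2 = config$tau2, gamma2 = config$gamma2,
    rho_w = config$rho_w, phi_b = config$phi_b,
    moderator = config$moderator, slopes = slopes,
    latent = dplyr::bind_rows(latents),
    v_blocks = v_blocks,
    clamp_rate = clamp_rate, n_repaired = n_repaired, seed = seed
  ), class = "sim_truth")
  list(data = data, truth = truth)
}

#' True sampling covariance of a simulated dataset
#'
#' Assembles the generator's own Level-1 covariance blocks (the large-sample
#' blocks evaluated at each sample's latent correlations) into a `cor_vmat`
#' aligned with the simulated dataset. This is the "known V" the model
#' assumes; fitting with it isolates estimator performance from the error of
#' plugging observed correlations into the covariance formulas.
#'
#' @param sim The list returned by [simulate_cor_data()].
#' @return A `cor_vmat` on the raw scale.
#' @export
vmat_true <- function(sim) {
  stopifnot(is.list(sim), inherits(sim$data, "cor_data"),
            inherits(sim$truth, "sim_truth"))
  vec <- cor_vectorize(sim$data)
  blocks <- list()
  for (sid in unique(vec$index$sample_id)) {
    cells <- vec$index$cell[vec$index$sample_id == sid]
    B <- sim$truth$v_blocks[[sid]]
    blocks[[sid]] <- B[cells, cells, drop = FALSE]
  }
  structure(list(blocks = blocks, index = vec$index, scale = "raw",
                 mode = "dependent", denominator = "n",
                 log = tibble::tibble(event = character(),
                                      sample_id = character(),
                                      cell = character(), value = double())),
            class = "cor_vmat")
}

# large-sample covariance block at given latent correlation vector
.olkin_block <- function(latent, roster, vars, n) {
  C <- length(latent)
  lk <- function(a, b) {
    if (a == b) return(1)
    i <- which((roster$var_a == a & roster$var_b == b) |
                 (roster$var_a == b & roster$var_b == a))
    latent[i]
  }
  B <- matrix(0, C, C)
  for (i in seq_len(C)) {
    B[i, i] <- (1 - latent[i]^2)^2 / n
    if (i < C) for (j in seq((i + 1), C)) {
      B[i, j] <- B[j, i] <- .pair_cov(roster$var_a[i], roster$var_b[i],
                                      roster$var_a[j], roster$var_b[j],
                                      lk, n, "n")
    }
  }
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12) B <- .psd_repair_block(B, floor = 1e-12)
  B
}

.rmvn1 <- function(Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  as.vector(L %*% stats::rnorm(nrow(Sigma)))
}

.draw_samples_per_study <- function(spec) {
  if (length(spec) == 1 && spec >= 1) return(as.integer(spec))
  sample.int(length(spec), 1, prob = spec)
}

.draw_n <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1) return(as.integer(spec))
  n <- stats::rlnorm(1, spec$meanlog, spec$sdlog)
  as.integer(round(pmin(pmax(n, spec$min), spec$max)))
}

.draw_moderator <- function(mod, level) {
  if (is.null(mod)) return(0)
  if (identical(mod$kind, "binary")) {
    stats::rbinom(1, 1, mod$prob %||% 0.5)
  } else {
    stats::rnorm(1, mod$mean %||% 0, mod$sd %||% 1)
  }
}

#' Parameter-recovery study
#'
#' Simulates `n_replicates` datasets from `config`, fits `model` to each, and
#' summarizes bias, RMSE and 95% confidence-interval coverage of the pooled
#' correlations (model-based and CR2 cluster-robust intervals) plus bias and
#' RMSE of the variance components. Non-convergent replicates are excluded
#' and counted.
#'
#' @param config A [sim_config()].
#' @param model A [working_model()] to fit (possibly deliberately
#'   misspecified).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed; per-replicate seeds are drawn from it.
#' @param robust Also compute CR2 robust coverage (slower; default `TRUE`).
#' @param vmat `"true"` (default) hands the fitter the generator's own
#'   Level-1 covariance blocks (the model treats V as known, so this is the
#'   well-specified condition); `"plugin"` rebuilds V from the observed
#'   correlations as an analyst would, folding plug-in error into the results.
#' @param control Optimizer control passed to [mlmv_fit()].
#' @return Tibble of class `mlmv_recovery`, one row per parameter: `parameter`,
#'   `truth`, `mean_est`, `bias`, `rmse`, `mc_se`, `coverage_model`,
#'   `coverage_robust`; attributes `n_converged`, `n_replicates`.
#' @export
parameter_recovery <- function(config, model, n_replicates = 100, seed = 1,
                               robust = TRUE, vmat = c("true", "plugin"),
                               control = list()) {
  stopifnot(inherits(config, "sim_config"), inherits(model, "working_model"))
  vmat <- match.arg(vmat)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  C <- nrow(config$roster)
  mu_true <- stats::setNames(config$mu, config$roster$label)
  tau2_true <- if (length(config$tau2) == 1) config$tau2 else
    stats::setNames(config$tau2, config$roster$label)
  gamma2_true <- if (length(config$gamma2) == 1) config$gamma2 else
    stats::setNames(config$gamma2, config$roster$label)

  res <- list()
  n_conv <- 0L
  for (i in seq_len(n_replicates)) {
    sim <- simulate_cor_data(config, seed = rep_seeds[i])
    vm <- if (vmat == "true") vmat_true(sim) else NULL
    f <- tryCatch(
      suppressWarnings(mlmv_fit(sim$data, model, vmat = vm,
                                control = control)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    n_conv <- n_conv + 1L
    td <- tidy(f, back_transform = TRUE)
    truth_beta <- mu_true[td$term]
    cover_m <- td$conf.low <= truth_beta & truth_beta <= td$conf.high
    cover_r <- rep(NA, nrow(td))
    if (robust) {
      rb <- tryCatch(suppressWarnings(robust_vcov(f)), error = function(e) NULL)
      if (!is.null(rb)) {
        lo <- rb$conf.low; hi <- rb$conf.high
        if (f$model$scale == "fisher_z") { lo <- tanh(lo); hi <- tanh(hi) }
        cover_r <- lo <= truth_beta & truth_beta <= hi
      }
    }
    res[[i]] <- tibble::tibble(
      parameter = c(td$term, paste0("tau2.", names(f$tau2)),
                    paste0("gamma2.", names(f$gamma2))),
      kind = c(rep("beta", nrow(td)), rep("tau2", length(f$tau2)),
               rep("gamma2", length(f$gamma2))),
      estimate = c(td$estimate, unname(f$tau2), unname(f$gamma2)),
      covered_model = c(cover_m, rep(NA, length(f$tau2) + length(f$gamma2))),
      covered_robust = c(cover_r, rep(NA, length(f$tau2) + length(f$gamma2)))
    )
  }
  if (n_conv == 0) stop("no replicate converged", call. = FALSE)
  all <- dplyr::bind_rows(res)
  truth_lookup <- function(param, kind) {
    if (kind == "beta") return(unname(mu_true[param]))
    if (kind == "tau2") {
      v <- tau2_true
      if (length(v) == 1) return(unname(v))
      return(unname(v[sub("^tau2\\.", "", param)]))
    }
    v <- gamma2_true
    if (length(v) == 1) return(unname(v))
    unname(v[sub("^gamma2\\.", "", param)])
  }
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$parameter, .data$kind),
    mean_est = mean(.data$estimate),
    sd_est = stats::sd(.data$estimate),
    coverage_model = mean(.data$covered_model),
    coverage_robust = mean(.data$covered_robust),
    n = dplyr::n(), .groups = "drop")
  out$truth <- mapply(truth_lookup, out$parameter, out$kind)
  out <- dplyr::mutate(
    out,
    bias = .data$mean_est - .data$truth,
    rmse = sqrt(.data$bias^2 + .data$sd_est^2 * (.data$n - 1) / .data$n),
    mc_se = .data$sd_est / sqrt(.data$n))
  out <- dplyr::select(out, "parameter", "kind", "truth", "mean_est", "bias",
                       "rmse", "mc_se", "coverage_model", "coverage_robust")
  attr(out, "n_converged") <- n_conv
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("mlmv_recovery", class(out))
  out
}
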