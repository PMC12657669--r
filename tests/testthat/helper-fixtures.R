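# small datasets built in code, shared across test files

# 2-study toy: study A has 1 sample with 3 cells, study B has 2 samples
toy_df <- function() {
  tibble::tibble(
    StudyID = c("A", "A", "A", "B", "B", "B", "B", "B", "B"),
    SampleID = c("s1", "s1", "s1", "s2", "s2", "s2", "s3", "s3", "s3"),
    Var1 = rep(c("X", "X", "Y"), 3),
    Var2 = rep(c("Y", "Z", "Z"), 3),
    Correlation = c(.30, .40, .50, .20, .30, .40, .25, .35, .45),
    N = rep(c(100, 200, 150), each = 3)
  )
}

toy_data <- function() cor_data(toy_df())

# 3-study dataset with 3 cells, mixed 1-2 samples per study, for oracles
oracle_data <- function(seed = 42) {
  sim <- simulate_cor_data(
    sim_config(n_variables = 3, n_studies = 3,
               samples_per_study = c(0.4, 0.6), n_per_sample = 120,
               tau2 = 0.01, gamma2 = 0.02),
    seed = seed)
  sim$data
}

# dense brute-force (restricted) log-likelihood from explicit indicator
# matrices -- the independent oracle for the block-wise implementation
dense_loglik <- function(data, vmat, tau2, gamma2, rho = 0, phi = 0,
                         method = "REML") {
  vec <- cor_vectorize(data)
  idx <- vec$index
  y <- vec$y
  N <- length(y)
  cells <- attr(data, "cells")$label[sort(unique(idx$cell_idx))]
  C <- length(cells)
  X <- outer(idx$cell, cells, `==`) * 1
  p <- ncol(X)

  re_cov <- function(v, cor) {
    v <- if (length(v) == 1) rep(v, C) else v
    G <- sqrt(outer(v, v)) * cor
    diag(G) <- v
    G
  }
  Tm <- re_cov(tau2, rho)
  Gm <- re_cov(gamma2, phi)

  # Z maps rows to (unit x cell) random effects, G is block diagonal over units
  z_block <- function(unit_ids) {
    units <- unique(unit_ids)
    Z <- matrix(0, N, length(units) * C)
    for (i in seq_len(N)) {
      u <- match(unit_ids[i], units)
      Z[i, (u - 1) * C + match(idx$cell[i], cells)] <- 1
    }
    Z
  }
  Zw <- z_block(idx$sample_id)
  Zb <- z_block(idx$study_id)
  Gw <- kronecker(diag(length(unique(idx$sample_id))), Tm)
  Gb <- kronecker(diag(length(unique(idx$study_id))), Gm)

  V <- as.matrix(vmat)
  M <- V + Zw %*% Gw %*% t(Zw) + Zb %*% Gb %*% t(Zb)
  Minv <- solve(M)
  A <- t(X) %*% Minv %*% X
  beta <- solve(A, t(X) %*% Minv %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Minv %*% r)
  if (method == "REML") {
    -0.5 * ((N - p) * log(2 * pi) + determinant(M)$modulus +
              determinant(A)$modulus + quad)
  } else {
    -0.5 * (N * log(2 * pi) + determinant(M)$modulus + quad)
  }
}

# evaluate the package's block-wise objective at given variance parameters
blockwise_loglik <- function(data, vmat, tau2, gamma2, rho = 0, phi = 0,
                             method = "REML") {
  model <- working_model(within = if (length(tau2) > 1) "HCS" else "CS",
                         between = if (length(gamma2) > 1) "HCS" else "CS",
                         rho = rho, phi = phi)
  vec <- cor_vectorize(data)
  y <- vec$y
  design <- mlmvcor:::.build_fixed_design(data, NULL)
  X <- design$X
  C <- length(design$cells_used)
  studies <- mlmvcor:::.prepare_studies(vec$index, vmat, design$cells_used)
  for (k in seq_along(studies)) {
    studies[[k]]$X <- X[studies[[k]]$rows, , drop = FALSE]
    studies[[k]]$y <- y[studies[[k]]$rows]
  }
  q_w <- if (length(tau2) > 1) C else 1L
  q_b <- if (length(gamma2) > 1) C else 1L
  -mlmvcor:::.neg_ll(log(c(tau2, gamma2)), y, X, studies, model, q_w, q_b, C,
                     method, ncol(X), length(y))
}
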