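test_that("working model catalogue and parameter counts", {
  wm1 <- working_model(1)
  expect_equal(c(wm1$within, wm1$between), c("HCS", "HCS"))
  wm2 <- working_model(2)
  expect_equal(c(wm2$within, wm2$between), c("HCS", "CS"))
  wm3 <- working_model(3)
  expect_equal(c(wm3$within, wm3$between), c("CS", "HCS"))
  wm4 <- working_model(4)
  expect_equal(c(wm4$within, wm4$between), c("CS", "CS"))
  C <- 10
  counts <- vapply(1:4, function(m) {
    wm <- working_model(m)
    mlmvcor:::.n_varpar(wm$within, C) + mlmvcor:::.n_varpar(wm$between, C)
  }, numeric(1))
  expect_equal(counts, c(2 * C, C + 1, C + 1, 2))
  # DIAG/ID force zero correlations
  expect_equal(working_model(within = "DIAG", between = "ID",
                             rho = .5, phi = .5)$rho, 0)
})

test_that("blockwise likelihood equals the dense brute-force oracle", {
  dat <- oracle_data()
  vmat <- build_vmat(dat)
  set.seed(31)
  for (i in 1:25) {
    tau2 <- runif(3, 1e-4, 0.05)
    gamma2 <- runif(3, 1e-4, 0.05)
    rho <- sample(c(0, 0.5), 1)
    phi <- sample(c(0, 0.5), 1)
    expect_equal(
      blockwise_loglik(dat, vmat, tau2, gamma2, rho, phi, "REML"),
      dense_loglik(dat, vmat, tau2, gamma2, rho, phi, "REML"),
      tolerance = 1e-8, ignore_attr = TRUE)
  }
  # shared-variance structures and ML variant
  for (i in 1:10) {
    tau2 <- runif(1, 1e-4, 0.05)
    gamma2 <- runif(1, 1e-4, 0.05)
    expect_equal(
      blockwise_loglik(dat, vmat, tau2, gamma2, 0, 0, "ML"),
      dense_loglik(dat, vmat, tau2, gamma2, 0, 0, "ML"),
      tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate single-row model matches the closed-form density", {
  df <- toy_df()[1, ]
  dat <- cor_data(df)
  vmat <- build_vmat(dat)
  v <- cor_variance(df$Correlation, df$N)
  # variances ~ 0: residual is 0 at beta = y, REML has N - p = 0 rows left
  ll <- blockwise_loglik(dat, vmat, 1e-13, 1e-13, 0, 0, "REML")
  expect_equal(ll, -0.5 * log(v) - 0.5 * log(1 / v), tolerance = 1e-6,
               ignore_attr = TRUE)
  ll_ml <- blockwise_loglik(dat, vmat, 1e-13, 1e-13, 0, 0, "ML")
  expect_equal(ll_ml, dnorm(0, sd = sqrt(v), log = TRUE), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("profile over a grid reproduces the univariate REML estimator", {
  # balanced one-cell case: single-sample studies, equal V -> REML of the
  # between-study variance has the closed form mean((y - ybar)^2) * K/(K-1) - v
  K <- 12
  set.seed(77)
  y <- 0.4 + rnorm(K, 0, 0.08)
  df <- tibble::tibble(StudyID = seq_len(K), SampleID = seq_len(K),
                       Var1 = "X", Var2 = "Y", Correlation = y, N = 500)
  dat <- cor_data(df)
  # equal sampling variances: force via independent blocks at a common value
  v <- mean(cor_variance(y, 500))
  vmat <- build_vmat(dat, mode = "independent")
  for (s in names(vmat$blocks)) vmat$blocks[[s]][1, 1] <- v
  grid <- seq(1e-5, 0.03, length.out = 400)
  ll <- vapply(grid,
               function(g) blockwise_loglik(dat, vmat, 1e-13, g, 0, 0, "REML"),
               numeric(1))
  ghat_grid <- grid[which.max(ll)]
  ghat_closed <- sum((y - mean(y))^2) / (K - 1) - v
  expect_equal(ghat_grid, ghat_closed, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("fitted models agree with metafor's rma.mv on the same V", {
  skip_if_not_installed("metafor")
  sim <- simulate_cor_data(sim_config(n_studies = 12), seed = 11)
  dat <- tibble::as_tibble(sim$data)
  vmat <- build_vmat(sim$data)
  V <- as.matrix(vmat)
  for (m in c(2, 4)) {
    f <- mlmv_fit(sim$data, working_model(m), vmat = vmat)
    struct <- list(`2` = c("HCS", "CS"), `4` = c("CS", "CS"))[[as.character(m)]]
    ref <- metafor::rma.mv(r ~ factor(cell) - 1, V = V,
                           random = list(~ factor(cell) | sample_id,
                                         ~ factor(cell) | study_id),
                           struct = struct, rho = 0, phi = 0, data = dat,
                           method = "REML", sparse = TRUE,
                           control = list(optimizer = "nlminb"))
    expect_equal(unname(f$beta), unname(as.vector(ref$beta)), tolerance = 1e-5)
    expect_equal(unname(sqrt(diag(f$vcov_beta))), unname(ref$se),
                 tolerance = 1e-4)
    expect_equal(unname(sort(f$tau2)), unname(sort(ref$tau2)),
                 tolerance = 1e-3)
    expect_equal(unname(f$gamma2), unname(ref$gamma2[1]), tolerance = 1e-3)
    expect_equal(f$qe, ref$QE, tolerance = 1e-6)
    expect_equal(f$qe_df, ref$QEdf)
  }
})

test_that("REML log-likelihoods respect the nesting hierarchy", {
  sim <- simulate_cor_data(sim_config(n_variables = 4, n_studies = 12),
                           seed = 3)
  vmat <- build_vmat(sim$data)
  ll <- vapply(1:4, function(m) {
    mlmv_fit(sim$data, working_model(m), vmat = vmat)$loglik
  }, numeric(1))
  expect_gte(ll[1], ll[2] - 1e-6)
  expect_gte(ll[1], ll[3] - 1e-6)
  expect_gte(ll[2], ll[4] - 1e-6)
  expect_gte(ll[3], ll[4] - 1e-6)
})

test_that("row permutation leaves the fit unchanged", {
  df <- tibble::as_tibble(simulate_cor_data(
    sim_config(n_variables = 3, n_studies = 8), seed = 9)$data)
  names(df)[match(c("study_id", "sample_id", "var_a", "var_b", "r", "n"),
                  names(df))] <-
    c("StudyID", "SampleID", "Var1", "Var2", "Correlation", "N")
  d1 <- cor_data(df, variable_order = c("V1", "V2", "V3"))
  set.seed(1)
  d2 <- cor_data(df[sample(nrow(df)), ], variable_order = c("V1", "V2", "V3"))
  f1 <- mlmv_fit(d1, working_model(2))
  f2 <- mlmv_fit(d2, working_model(2))
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$loglik, f2$loglik)
  expect_equal(f1$tau2, f2$tau2)
})

test_that("homogeneous data pin variances at the boundary", {
  sim <- simulate_cor_data(
    sim_config(n_variables = 3, n_studies = 15, tau2 = 0, gamma2 = 0,
               n_per_sample = 800, mode = "asymptotic"),
    seed = 21)
  f <- mlmv_fit(sim$data, working_model(4))
  expect_true(all(f$tau2 < 1e-4))
  expect_true(all(f$gamma2 < 1e-4))
  expect_true(any(f$boundary))
  # beta approximately the fixed-effects GLS solution
  qe_fit <- mlmv_fit(sim$data, working_model(4),
                     vmat = build_vmat(sim$data))
  expect_equal(unname(qe_fit$beta), rep(0.4, 3), tolerance = 0.03)
})

test_that("single-sample-per-study data warn about identification", {
  sim <- simulate_cor_data(
    sim_config(n_variables = 3, n_studies = 10, samples_per_study = 1),
    seed = 2)
  expect_warning(mlmv_fit(sim$data, working_model(4)), "identified only in sum")
})

test_that("rank-deficient fixed designs and scale mismatches are caught", {
  sim <- simulate_cor_data(sim_config(n_variables = 3, n_studies = 6), seed = 4)
  vz <- build_vmat(sim$data, scale = "fisher_z")
  expect_error(mlmv_fit(sim$data, working_model(2), vmat = vz),
               "does not match the model scale")
  fz <- mlmv_fit(sim$data, working_model(2, scale = "fisher_z"), vmat = vz)
  td_z <- tidy(fz, back_transform = TRUE)
  td_r <- tidy(mlmv_fit(sim$data, working_model(2)))
  expect_equal(td_z$estimate, td_r$estimate, tolerance = 0.02)
})
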