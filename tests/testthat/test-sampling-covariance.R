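test_that("large-sample variance formula matches known values", {
  expect_equal(cor_variance(0, 100), 0.01)
  expect_equal(cor_variance(0.5, 25), (0.75^2) / 25)
  expect_equal(cor_variance(0.9, 100), (0.19^2) / 100)
  expect_error(cor_variance(1, 100), "strictly inside")
  expect_error(cor_variance(0.2, 3), ">= 5")
  expect_equal(cor_variance(0.5, 26, denominator = "n-1"),
               cor_variance(0.5, 25))
})

test_that("shared-variable covariance: zeros, worked value, variance limit", {
  expect_equal(cor_covariance_shared(0, 0, 0, 50), 0)
  expect_equal(cor_covariance_shared(0.5, 0, 0, 100), 0.005)
  # when the two coefficients coincide (t = u, rho_tu = 1) it is the variance
  for (rho in c(-0.3, 0.2, 0.7)) {
    expect_equal(cor_covariance_shared(0.999999, rho, rho, 80),
                 cor_variance(rho, 80), tolerance = 1e-4)
  }
  # symmetric in the two coefficients
  expect_equal(cor_covariance_shared(0.4, 0.2, 0.6, 100),
               cor_covariance_shared(0.4, 0.6, 0.2, 100))
})

test_that("general covariance: zeros, worked value, and symmetries", {
  expect_equal(cor_covariance_general(0, 0, 0, 0, 0, 0, 77), 0)
  expect_equal(cor_covariance_general(0, 0, 0.5, 0, 0, 0.5, 100), 0.0025)
  r <- list(st = .3, uv = .4, su = .1, sv = .2, tu = .25, tv = .15)
  base <- cor_covariance_general(r$st, r$uv, r$su, r$sv,
                                 r$tu, r$tv, 60)
  # swap s <-> t
  expect_equal(cor_covariance_general(r$st, r$uv, r$tu, r$tv,
                                      r$su, r$sv, 60), base)
  # swap (s,t) <-> (u,v)
  expect_equal(cor_covariance_general(r$uv, r$st, r$su, r$tu,
                                      r$sv, r$tv, 60), base)
  # reduces to the shared-variable formula at u = s (rho_su = 1)
  expect_equal(
    cor_covariance_general(r$st, r$sv, 0.999999, r$sv, r$st,
                           r$tv, 60),
    cor_covariance_shared(r$tv, r$st, r$sv, 60), tolerance = 1e-4)
})

test_that("Fisher z transform and variance", {
  expect_equal(r_to_z(0), 0)
  expect_equal(r_to_z(0.5), atanh(0.5))
  expect_equal(round(r_to_z(0.5), 4), 0.5493)
  expect_equal(z_variance(103), 0.01)
  expect_equal(z_to_r(r_to_z(0.77)), 0.77)
})

test_that("block construction: modes, scales, and structural zeros", {
  dat <- toy_data()
  v_ind <- build_vmat(dat, mode = "independent")
  for (B in v_ind$blocks) {
    expect_true(all(B[upper.tri(B)] == 0))
  }
  expect_equal(diag(v_ind$blocks[["s1"]]),
               cor_variance(c(.30, .40, .50), 100),
               ignore_attr = TRUE)

  # all-zero correlations with a shared variable: off-diagonals vanish
  df0 <- toy_df()[1:3, ]
  df0$Correlation <- 0
  d0 <- cor_data(df0)
  v0 <- build_vmat(d0, mode = "dependent")
  expect_equal(v0$blocks[["s1"]], diag(0.01, 3), ignore_attr = TRUE)

  # full 5-variable matrix gives a 10 x 10 block
  sim <- simulate_cor_data(sim_config(n_studies = 1, samples_per_study = 1,
                                      n_per_sample = 400), seed = 1)
  vb <- build_vmat(sim$data)
  expect_equal(dim(vb$blocks[[1]]), c(10, 10))
  ev <- eigen(vb$blocks[[1]], symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)

  # assembled matrix is exactly block diagonal
  V <- as.matrix(build_vmat(dat))
  expect_equal(V[1:3, 4:9], matrix(0, 3, 6))
})

test_that("Fisher-z blocks converge to n/(n-3)-scaled raw blocks as r -> 0", {
  df <- toy_df()
  df$Correlation <- df$Correlation / 100
  dat <- cor_data(df)
  vr <- build_vmat(dat, scale = "raw")
  vz <- build_vmat(dat, scale = "fisher_z")
  n <- 100
  expect_equal(vz$blocks[["s1"]], vr$blocks[["s1"]] * n / (n - 3),
               tolerance = 0.01)
})

test_that("dependent blocks agree with metafor's rcalc construction", {
  skip_if_not_installed("metafor")
  sim <- simulate_cor_data(sim_config(n_studies = 4), seed = 5)
  dat <- tibble::as_tibble(sim$data)
  mine <- build_vmat(sim$data, denominator = "n-1") # rcalc's convention
  ref <- metafor::rcalc(r ~ var_a + var_b | sample_id, ni = n, data = dat)
  for (sid in names(mine$blocks)) {
    rows <- which(ref$dat$sample_id == sid)
    expect_equal(unname(as.matrix(ref$V[rows, rows])),
                 unname(mine$blocks[[sid]]), tolerance = 1e-10)
  }
})

test_that("plug-in policy resolves correlations missing from a sample", {
  # sample s1 observes only X-Y and X-Z; the (X-Y, X-Z) covariance needs Y-Z,
  # which must come from the n-weighted mean across samples
  df <- toy_df()[-3, ]
  dat <- cor_data(df)
  v <- build_vmat(dat, plugin = "weighted_mean")
  expect_true(any(v$log$event == "plugin"))
  yz <- v$log[v$log$event == "plugin" & v$log$sample_id == "s1", ]
  wmean <- sum(c(.40, .45) * c(200, 150)) / 350
  expect_equal(yz$value, wmean)
  b <- v$blocks[["s1"]]
  expect_equal(b["X–Y", "X–Z"],
               cor_covariance_shared(wmean, .30, .40, 100))
  v0 <- build_vmat(dat, plugin = "zero")
  expect_equal(v0$blocks[["s1"]]["X–Y", "X–Z"],
               cor_covariance_shared(0, .30, .40, 100))
})

test_that("sparse export/import round-trips the matrix", {
  dat <- toy_data()
  v <- build_vmat(dat)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vmat(v, path)
  v2 <- read_vmat(path, dat)
  expect_equal(v2$blocks, v$blocks, tolerance = 1e-12)
  expect_equal(v2$scale, v$scale)
})

test_that("Monte-Carlo oracle: constructed covariances match simulation", {
  # 3-variable true correlation matrix, moderate correlations
  R <- matrix(c(1, .5, .3,
                .5, 1, .4,
                .3, .4, 1), 3, 3)
  n <- 500
  reps <- 8000
  L <- chol(R)
  set.seed(101)
  rs <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    Zm <- matrix(rnorm(n * 3), n, 3) %*% L
    cc <- cor(Zm)
    rs[i, ] <- c(cc[1, 2], cc[1, 3], cc[2, 3])
  }
  emp <- cov(rs)
  form <- matrix(0, 3, 3)
  form[1, 1] <- cor_variance(R[1, 2], n)
  form[2, 2] <- cor_variance(R[1, 3], n)
  form[3, 3] <- cor_variance(R[2, 3], n)
  form[1, 2] <- cor_covariance_shared(R[2, 3], R[1, 2], R[1, 3], n) # share var 1
  form[1, 3] <- cor_covariance_shared(R[1, 3], R[1, 2], R[2, 3], n) # share var 2
  form[2, 3] <- cor_covariance_shared(R[1, 2], R[1, 3], R[2, 3], n) # share var 3
  form[lower.tri(form)] <- t(form)[lower.tri(form)]
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((emp[i, i] * emp[j, j] + emp[i, j]^2) / reps)
    tol <- max(0.10 * abs(form[i, j]), 3 * se)
    expect_lt(abs(emp[i, j] - form[i, j]), tol)
  }
})
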