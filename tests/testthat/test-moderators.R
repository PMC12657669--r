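# dataset with a sample-level binary moderator whose true effect is negative
# on every cell, plus a pure-noise continuous column
mod_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_variables = 3, n_studies = 40, samples_per_study = 2,
        n_per_sample = 400, tau2 = 0.004, gamma2 = 0.004,
        moderator = list(name = "clinical", kind = "binary", level = "sample",
                         prob = 0.4, slope = -0.08))
      sim <- simulate_cor_data(cfg, seed = 17)
      df <- tibble::as_tibble(sim$data)
      set.seed(18)
      per_sample <- unique(df$sample_id)
      noise <- stats::setNames(rnorm(length(per_sample), 50, 10), per_sample)
      df$noise_mod <- noise[df$sample_id]
      names(df)[match(c("study_id", "sample_id", "var_a", "var_b", "r", "n"),
                      names(df))] <-
        c("StudyID", "SampleID", "Var1", "Var2", "Correlation", "N")
      cache <<- list(data = cor_data(df, variable_order = paste0("V", 1:3)),
                     truth = sim$truth)
    }
    cache
  }
})

test_that("design construction yields the documented column counts", {
  dat <- mod_sim()$data
  C <- 3
  d_int <- mlmvcor:::.build_fixed_design(
    dat, moderator_spec("clinical", "categorical", "interaction"))
  expect_equal(ncol(d_int$X), 2 * C) # C cell mains + C x (2 - 1) interactions
  d_sub <- mlmvcor:::.build_fixed_design(
    dat, moderator_spec("clinical", "categorical", "subgroup"))
  expect_equal(ncol(d_sub$X), 2 * C) # C x L
  d_cont <- mlmvcor:::.build_fixed_design(
    dat, moderator_spec("noise_mod", "continuous"))
  expect_equal(ncol(d_cont$X), 2 * C) # C cells + C slopes
  expect_true(all(grepl(":noise_mod$", colnames(d_cont$X)[(C + 1):(2 * C)])))
})

test_that("moderated fit recovers a negative moderator effect per cell", {
  ms <- mod_sim()
  fit <- fit_moderated(ms$data, moderator_spec("clinical"),
                       model = working_model(2))
  td <- tidy(fit)
  inter <- td[grepl(":clinical", td$term), ]
  expect_equal(nrow(inter), 3)
  for (i in seq_len(3)) {
    expect_lt(abs(inter$estimate[i] - (-0.08)), 3 * inter$std.error[i])
  }
  expect_true(all(inter$estimate < 0))
})

test_that("subgroup and interaction parameterizations are equivalent", {
  ms <- mod_sim()
  vm <- build_vmat(ms$data)
  f_int <- fit_moderated(ms$data, moderator_spec("clinical"), vmat = vm,
                         model = working_model(2))
  f_sub <- fit_moderated(ms$data,
                         moderator_spec("clinical",
                                        parameterization = "subgroup"),
                         vmat = vm, model = working_model(2))
  expect_equal(f_int$loglik, f_sub$loglik, tolerance = 1e-6)
  # group-0 estimates equal the cell mains; group-1 equal main + interaction
  b_int <- f_int$beta
  b_sub <- f_sub$beta
  cells <- f_int$cells
  for (cl in cells) {
    expect_equal(unname(b_sub[paste0(cl, ":clinical0")]),
                 unname(b_int[cl]), tolerance = 1e-5)
    expect_equal(unname(b_sub[paste0(cl, ":clinical1")]),
                 unname(b_int[cl] + b_int[paste0(cl, ":clinical1")]),
                 tolerance = 1e-5)
  }
})

test_that("a between-group contrast reproduces the interaction coefficient", {
  ms <- mod_sim()
  f_sub <- fit_moderated(ms$data,
                         moderator_spec("clinical",
                                        parameterization = "subgroup"),
                         model = working_model(2))
  L <- c(-1, 1)
  names(L) <- c("V1–V2:clinical0", "V1–V2:clinical1")
  ct <- contrast_test(f_sub, L)
  f_int <- fit_moderated(ms$data, moderator_spec("clinical"),
                         model = working_model(2))
  td <- tidy(f_int)
  ref <- td[td$term == "V1–V2:clinical1", ]
  expect_equal(unname(ct$estimate), ref$estimate, tolerance = 1e-5)
  expect_equal(unname(ct$std.error), ref$std.error, tolerance = 1e-4)
})

test_that("variance explained: identity, manual formula, truncation flags", {
  ms <- mod_sim()
  vm <- build_vmat(ms$data)
  f_null <- mlmv_fit(ms$data, working_model(2), vmat = vm)
  f_mod <- fit_moderated(ms$data, moderator_spec("clinical"), vmat = vm,
                         model = working_model(2))
  ve <- variance_explained(f_null, f_mod)
  expect_equal(nrow(ve), 3 + 1) # per-cell within + shared between
  manual_within <- pmax(0, (f_null$tau2 - f_mod$tau2) / f_null$tau2)
  expect_equal(ve$r2[ve$level == "within"], unname(manual_within))
  manual_between <- max(0, (f_null$gamma2 - f_mod$gamma2) / f_null$gamma2)
  expect_equal(ve$r2[ve$level == "between"], manual_between)
  expect_true(all(ve$r2 >= 0 & ve$r2 <= 1, na.rm = TRUE))
  expect_equal(ve$truncated,
               unname(c(f_mod$tau2 > f_null$tau2,
                        f_mod$gamma2 > f_null$gamma2)))
  # the sample-level moderator should explain some within-study variance
  expect_gt(mean(ve$r2[ve$level == "within"]), 0.1)
  # structural mismatch is a hard error
  f4 <- mlmv_fit(ms$data, working_model(4), vmat = vm)
  expect_error(variance_explained(f4, f_mod), "share variance structures")
})

test_that("pure-noise moderator leaves pooled estimates essentially unchanged", {
  ms <- mod_sim()
  vm <- build_vmat(ms$data)
  f_null <- mlmv_fit(ms$data, working_model(2), vmat = vm)
  f_noise <- fit_moderated(ms$data,
                           moderator_spec("noise_mod", center = TRUE),
                           vmat = vm, model = working_model(2))
  td <- tidy(f_noise)
  cells <- f_null$cells
  for (cl in cells) {
    expect_lt(abs(td$estimate[td$term == cl] - f_null$beta[cl]),
              2.5 * sqrt(diag(f_null$vcov_beta))[cl])
  }
  slopes <- td[grepl(":noise_mod", td$term), ]
  expect_true(all(abs(slopes$statistic) < 4))
})

test_that("degenerate moderator inputs are rejected", {
  ms <- mod_sim()
  df <- tibble::as_tibble(ms$data)
  names(df)[match(c("study_id", "sample_id", "var_a", "var_b", "r", "n"),
                  names(df))] <-
    c("StudyID", "SampleID", "Var1", "Var2", "Correlation", "N")
  df$flat <- 1
  dat <- cor_data(df, variable_order = paste0("V", 1:3))
  expect_error(fit_moderated(dat, moderator_spec("flat")), "constant")
  expect_error(fit_moderated(dat, moderator_spec("nope")), "not found")
  # moderator duplicating a cell indicator forces rank deficiency
  df$dup <- as.numeric(dat$cell == "V1–V2")
  dat2 <- cor_data(df, variable_order = paste0("V", 1:3))
  expect_error(
    fit_moderated(dat2, moderator_spec("dup", kind = "continuous")),
    "rank deficient")
})

test_that("rows with missing moderator values are dropped with a message", {
  ms <- mod_sim()
  df <- tibble::as_tibble(ms$data)
  names(df)[match(c("study_id", "sample_id", "var_a", "var_b", "r", "n"),
                  names(df))] <-
    c("StudyID", "SampleID", "Var1", "Var2", "Correlation", "N")
  df$clinical[df$SampleID %in% df$SampleID[1]] <- NA
  dat <- cor_data(df, variable_order = paste0("V", 1:3))
  expect_message(
    f <- fit_moderated(dat, moderator_spec("clinical"),
                       model = working_model(4)),
    "dropped")
  expect_equal(f$nobs, nrow(dat) - 3)
})
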