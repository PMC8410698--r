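test_that("stratified folds preserve class balance and partition the data", {
  labels <- rep(c("normal", "abnormal"), each = 100)
  folds <- make_folds(labels, k = 10, seed = 1)
  expect_length(folds, 10L)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:200)           # cover, disjoint
  expect_equal(sum(lengths(tests)), 200L)
  for (f in folds) {
    expect_length(f$test, 20L)
    expect_equal(as.integer(table(labels[f$test])), c(10L, 10L))
    expect_equal(sort(c(f$train, f$test)), 1:200)
  }
  # reproducible given the seed
  expect_identical(folds, make_folds(labels, k = 10, seed = 1))
  expect_error(make_folds(rep(c("a", "b"), c(5, 100)), k = 10), "smallest class")
})

test_that("leave-one-batch-out folds are the batch index sets", {
  labels <- rep(c("a", "b"), 15)
  batches <- rep(c("b1", "b2", "b3"), each = 10)
  folds <- make_folds(labels, scheme = "lobo", batches = batches)
  expect_length(folds, 3L)
  expect_equal(folds[[2]]$test, 11:20)
  expect_equal(folds[[2]]$train, c(1:10, 21:30))
  expect_error(make_folds(labels, scheme = "lobo"), "batch")
})

test_that("mean sensitivity averages per-class recall", {
  expect_equal(mean_sensitivity(diag(c(7, 9, 4))), 1)
  expect_equal(mean_sensitivity(matrix(c(9, 2, 1, 8), 2, 2)), 0.85)
  expect_warning(v <- mean_sensitivity(matrix(c(5, 0, 5, 0), 2, 2)),
                 "empty")
  expect_equal(v, 0.5)
  # random uniform predictions on balanced 3-class data: about 1/3
  set.seed(1)
  ms <- replicate(1000, {
    truth <- factor(rep(1:3, each = 30), levels = 1:3)
    pred <- factor(sample(1:3, 90, replace = TRUE), levels = 1:3)
    mean_sensitivity(table(truth, pred))
  })
  expect_equal(mean(ms), 1 / 3, tolerance = 0.02)
})

test_that("Kruskal-Wallis matches a brute-force rank computation", {
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$statistic, kw_brute(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-10)
  expect_equal(kw$p.value, 1 - pchisq(kw$statistic, 1), tolerance = 1e-12)
  # with ties
  a <- c(1, 1, 2, 3.5)
  b <- c(2, 3.5, 3.5, 5)
  expect_equal(kruskal_wallis(a, b)$statistic, kw_brute(a, b),
               tolerance = 1e-10)
  # identical samples: no evidence, not an error
  expect_equal(kruskal_wallis(c(1, 1), c(1, 1, 1)),
               list(statistic = 0, p.value = 1))
  # rank statistic is invariant under strictly monotone transforms
  set.seed(2)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(kruskal_wallis(x, y)$statistic,
               kruskal_wallis(exp(x), exp(y))$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(numeric(0), 1:3), "non-empty")
})

test_that("full-rank PCA-LDA equals LDA on the raw centered spectra", {
  set.seed(3)
  sp <- spectra_set(matrix(rnorm(40 * 10), 40, 10) +
                      rep(rep(c(0, 1), each = 20), 10),
                    labels = rep(c("a", "b"), each = 20))
  folds <- make_folds(sp$labels, k = 4, seed = 9)
  res <- run_method_cv(sp, "pca_lda", n_components = 10, folds = folds)
  # direct route: LDA on raw data, fold by fold
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    mod <- lda_fit(sp$intensities[tr, ], sp$labels[tr])
    pred <- lda_predict(mod, sp$intensities[te, ])
    conf <- unclass(table(factor(sp$labels[te], c("a", "b")),
                          factor(pred, c("a", "b"))))
    expect_equal(res$fold_confusion[[f]], conf, ignore_attr = TRUE)
  }
})

test_that("cross-validation results are reproducible and well-formed", {
  sim <- simulate_raman(raman_sim_config(n_per_class = 20, n_points = 128,
                                         snr = 10, seed = 4))
  r1 <- run_method_cv(sim, "fpca_lda", n_components = 8, k = 5, seed = 2,
                      n_basis = 30)
  r2 <- run_method_cv(sim, "fpca_lda", n_components = 8, k = 5, seed = 2,
                      n_basis = 30)
  expect_identical(r1$fold_sensitivity, r2$fold_sensitivity)
  expect_length(r1$fold_confusion, 5L)
  for (f in 1:5) expect_equal(sum(r1$fold_confusion[[f]]), 8)  # fold size
  expect_true(all(r1$fold_sensitivity >= 0 & r1$fold_sensitivity <= 1))
  expect_equal(r1$mean_sensitivity, mean(r1$fold_sensitivity))
  expect_error(run_method_cv(sim, "pca_lda", n_components = 50, k = 5),
               "exceeds training size")
})

test_that("grid comparison produces one complete row per configuration", {
  configs <- list(
    raman_sim_config(shift = 0.05, snr = 100, n_per_class = 20,
                     n_points = 128, seed = 11),
    raman_sim_config(shift = 0.05, snr = 0.5, n_per_class = 20,
                     n_points = 128, seed = 12)
  )
  grid <- run_grid_comparison(configs, n_components = 8, n_basis = 30, k = 5)
  expect_s3_class(grid, "comparison_grid")
  expect_equal(nrow(grid), 2L)
  expect_equal(names(grid), c("shift", "snr", "sens_pca", "sd_pca",
                              "sens_fpca", "sd_fpca", "diff", "kw_p"))
  expect_equal(grid$diff, grid$sens_fpca - grid$sens_pca)
  expect_true(all(grid$kw_p >= 0 & grid$kw_p <= 1))
  # easier cell (high SNR) at least as separable as the hard one
  expect_gte(grid$sens_pca[1], grid$sens_pca[2])
  expect_gte(grid$sens_fpca[1], grid$sens_fpca[2])
})

test_that("a failing grid cell is recorded as missing, not fatal", {
  configs <- list(raman_sim_config(shift = 0.05, snr = 100, n_per_class = 5,
                                   n_points = 64, seed = 13))
  # n_components far beyond what 5 spectra per class can support
  expect_warning(grid <- run_grid_comparison(configs, n_components = 50,
                                             n_basis = 20, k = 2),
                 "failed")
  expect_true(is.na(grid$sens_pca[1]))
  expect_equal(grid$shift[1], 0.05)
})
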