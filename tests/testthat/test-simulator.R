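test_that("default simulation has the study dimensions and labels", {
  sim <- simulate_raman(raman_sim_config(seed = 5))
  expect_s3_class(sim, "spectra_set")
  expect_equal(dim(sim$intensities), c(200L, 1024L))
  expect_equal(as.integer(table(sim$labels)[c("normal", "abnormal")]),
               c(100L, 100L))
  expect_equal(length(sim$grid), 1024L)
  expect_true(all(diff(sim$grid) > 0))
  expect_equal(dim(attr(sim, "clean")), c(200L, 1024L))
})

test_that("identical configurations give bitwise-identical datasets", {
  cfg <- raman_sim_config(shift = 0.01, snr = 5, background = TRUE, seed = 99)
  a <- simulate_raman(cfg)
  b <- simulate_raman(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(attr(a, "clean"), attr(b, "clean"))
})

test_that("invalid configurations are rejected", {
  expect_error(raman_sim_config(snr = 0), "snr")
  expect_error(raman_sim_config(snr = -3), "snr")
  expect_error(raman_sim_config(shift = 0.6), "domain")
  expect_error(raman_sim_config(peak_widths = c(0.01, -0.1, 0.01)), "positive")
})

test_that("injected noise level matches the SNR definition", {
  snr <- 10
  sim <- simulate_raman(raman_sim_config(shift = 0, snr = snr, seed = 21))
  clean <- attr(sim, "clean")
  amax <- max(clean)
  resid <- sim$intensities - clean   # pure noise by construction
  # estimate sigma over a peak-free window from a subset of spectra
  window <- sim$grid > 0.85
  est <- sd(resid[1:20, window])
  n_used <- sum(window) * 20
  se <- (amax / snr) / sqrt(2 * n_used)
  expect_lt(abs(est - amax / snr), 3 * se)
})

test_that("residual variance decreases as configured SNR rises", {
  vars <- sapply(c(0.5, 5, 50), function(sn) {
    sim <- simulate_raman(raman_sim_config(snr = sn, seed = 77))
    var(as.numeric(sim$intensities - attr(sim, "clean")))
  })
  expect_true(all(diff(vars) < 0))
})

test_that("zero shift makes the two classes exchangeable", {
  sim <- simulate_raman(raman_sim_config(shift = 0, snr = 100, seed = 31))
  clean <- attr(sim, "clean")
  expect_identical(clean[1, ], clean[101, ])
  # per-point two-sample KS tests reject at about the nominal 5% rate
  set.seed(1)
  pts <- sample(1024, 60)
  rej <- sum(sapply(pts, function(j) {
    suppressWarnings(ks.test(sim$intensities[1:100, j],
                             sim$intensities[101:200, j])$p.value) < 0.05
  }))
  expect_lte(rej, qbinom(0.999, 60, 0.05) + 1)
})

test_that("the study grid covers 7 x 9 = 63 distinct cases deterministically", {
  g1 <- simulation_grid(seed = 1)
  g2 <- simulation_grid(seed = 1)
  expect_length(g1, 63L)
  pairs <- unique(t(sapply(g1, function(c) c(c$shift, c$snr))))
  expect_equal(nrow(pairs), 63L)
  expect_identical(sapply(g1, `[[`, "seed"), sapply(g2, `[[`, "seed"))
  expect_true(all(sapply(g1, function(c) c$n_per_class == 100L &&
                           c$n_points == 1024L)))
  sim <- simulate_raman(g1[[17]])
  expect_equal(dim(sim$intensities), c(200L, 1024L))
})

test_that("zero-scale background leaves spectra untouched", {
  sim <- make_test_spectra(10, 40, seed = 2)
  expect_identical(add_background(sim, scale = 0)$intensities,
                   sim$intensities)
})

test_that("random backgrounds are non-negative with calibrated height", {
  set.seed(8)
  grid <- seq(0, 1, length.out = 256)
  bg <- random_background(500, grid, peak_max = 1, max_range = c(0.5, 2))
  expect_true(all(bg >= 0))
  peaks <- apply(bg, 1, max)
  expect_true(all(peaks <= 2 + 1e-9))
  # maxima uniform on [0.5, 2] x peak amplitude: check the mean
  expect_equal(mean(peaks), 1.25, tolerance = 0.05)
})

test_that("background addition raises mean intensity by the mean background level", {
  sim <- simulate_raman(raman_sim_config(snr = 30, seed = 12,
                                         n_per_class = 500, n_points = 256))
  with_bg <- add_background(sim, peak_max = 1, seed = 13)
  observed_lift <- mean(with_bg$intensities) - mean(sim$intensities)
  # independent Monte-Carlo estimate of the generator's mean level
  set.seed(14)
  ref <- mean(random_background(1000, sim$grid, peak_max = 1))
  expect_equal(observed_lift, ref, tolerance = 0.05 * ref + 0.02)
  # per-spectrum minima shift upward on average
  expect_gt(mean(apply(with_bg$intensities, 1, min) -
                 apply(sim$intensities, 1, min)), 0)
})

test_that("backgrounds are much smoother than the sharpest peak", {
  set.seed(9)
  grid <- seq(0, 1, length.out = 1024)
  bg <- random_background(100, grid, peak_max = 1)
  curv_bg <- max(abs(apply(bg, 1, function(r) max(abs(diff(r, differences = 2))))))
  cfg <- raman_sim_config()
  peak <- gaussian_peak <- cfg$peak_amplitudes[1] *
    exp(-(grid - cfg$peak_positions[1])^2 / (2 * cfg$peak_widths[1]^2))
  curv_peak <- max(abs(diff(peak, differences = 2)))
  expect_gt(curv_peak, 10 * curv_bg)
})

test_that("SNR estimation behaves like a peak-over-noise ratio", {
  grid <- seq(0, 1, length.out = 512)
  expect_error(estimate_snr(rep(2, 512), grid, 0.5, c(0.8, 0.9)),
               "zero variance")
  expect_error(estimate_snr(rnorm(512), grid, 0.5, c(0.8, 0.801)),
               "3 grid points")
  clean <- exp(-(grid - 0.3)^2 / (2 * 0.02^2))
  set.seed(4)
  ests <- replicate(200, {
    y <- clean + rnorm(512, sd = 0.1)
    estimate_snr(y, grid, 0.3, c(0.7, 0.95))
  })
  expect_equal(mean(ests), 10, tolerance = 0.5)
  # ratio is invariant to positive rescaling
  set.seed(5)
  y <- clean + rnorm(512, sd = 0.1)
  expect_equal(estimate_snr(3.7 * y, grid, 0.3, c(0.7, 0.95)),
               estimate_snr(y, grid, 0.3, c(0.7, 0.95)))
})
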