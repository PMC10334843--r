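test_that("noiseless decays are recovered to solver tolerance", {
  h <- simulate_decay(0.7, 0.4, 2.5, 1e5, default_irf, noiseless = TRUE)
  f <- fit_decay(h)
  expect_true(f$converged)
  expect_lt(abs(f$a1 - 0.7), 1e-3)
  expect_lt(abs(f$t1 - 0.4) / 0.4, 1e-3)
  expect_lt(abs(f$t2 - 2.5) / 2.5, 1e-3)
  expect_identical(f$a1 + f$a2, 1)
})

test_that("fits respect the photon floor and the lifetime ordering", {
  h <- simulate_decay(0.7, 0.4, 2.5, 150, default_irf, seed = 1)
  expect_error(fit_decay(h), "min_counts")
  h2 <- simulate_decay(0.5, 0.3, 3.0, 5e4, default_irf, seed = 2)
  f <- fit_decay(h2)
  expect_lt(f$t1, f$t2)
  expect_gte(f$a1, 0)
  expect_lte(f$a1, 1)
})

test_that("fits are invariant to intensity scaling of the histogram", {
  h1 <- simulate_decay(0.65, 0.45, 2.3, 1e4, default_irf, noiseless = TRUE)
  h10 <- simulate_decay(0.65, 0.45, 2.3, 1e5, default_irf, noiseless = TRUE)
  f1 <- fit_decay(h1); f10 <- fit_decay(h10)
  expect_equal(f1$a1, f10$a1, tolerance = 1e-6)
  expect_equal(f1$t2, f10$t2, tolerance = 1e-6)
})

test_that("recovery error shrinks monotonically with photon count", {
  rmse <- sapply(c(1e3, 1e4, 1e5), function(N) {
    errs <- sapply(1:25, function(r) {
      h <- simulate_decay(0.7, 0.4, 2.5, N, default_irf,
                          seed = child_seed(31, r + N))
      f <- fit_decay(h, min_counts = 100)
      c(f$a1 - 0.7, (f$t2 - 2.5) / 2.5)
    })
    sqrt(rowMeans(errs^2))
  })
  expect_true(all(diff(rmse[1, ]) < 0))   # a1 RMSE decreasing
  expect_true(all(diff(rmse[2, ]) < 0))   # t2 relative RMSE decreasing
})

test_that("the likelihood objective is unbiased at low counts", {
  est <- sapply(1:30, function(r) {
    h <- simulate_decay(0.7, 0.4, 2.5, 2000, default_irf, seed = child_seed(5, r))
    f <- fit_decay(h, min_counts = 100, objective = "mle")
    c(f$a1, f$t2)
  })
  expect_lt(abs(mean(est[1, ]) - 0.7), 0.015)
  expect_lt(abs(mean(est[2, ]) - 2.5) / 2.5, 0.03)
})

test_that("mean lifetime of fits on mono-exponential truth recovers tau", {
  t_ns <- (seq_len(256) - 0.5) * default_irf$bin_width_ps / 1000
  d <- exp(-t_ns / 1.5)
  y <- adipoflim:::convolve_linear(default_irf$curve, d)
  h <- 5e4 * y / sum(y)
  f <- fit_decay(h, irf = default_irf)
  expect_equal(mean_lifetime(f), 1.5, tolerance = 0.02)
})

test_that("reduced chi-square matches hand arithmetic and is calibrated", {
  expect_equal(reduced_chi2(c(10, 20, 30), c(10, 20, 30), n_params = 1), 0)
  obs <- c(12, 18, 33, 28, 9)
  expec <- c(10, 20, 30, 30, 10)
  hand <- (4 / 10 + 4 / 20 + 9 / 30 + 4 / 30 + 1 / 10) / (5 - 2)
  expect_equal(reduced_chi2(obs, expec, n_params = 2), hand)
  expect_error(reduced_chi2(obs, expec, n_params = 5), "degrees of freedom")
  expect_error(reduced_chi2(obs, expec[-1], n_params = 1), "grid")

  # well-specified fits: use the likelihood objective, whose estimates are
  # unbiased, so Pearson chi-square is calibrated at moderate counts
  chis <- sapply(1:60, function(r) {
    h <- simulate_decay(0.7, 0.4, 2.5, 1e4, default_irf, seed = child_seed(91, r))
    fit_decay(h, objective = "mle")$chi2r
  })
  expect_lt(abs(mean(chis) - 1), 0.1)
})

test_that("image-wise fitting maps a uniform frame back to its truth", {
  di <- uniform_decay_image(frame = 10, a1 = 0.7, t1 = 0.4, t2 = 2.5,
                            counts_per_pixel = 2000, seed = 21)
  maps <- fit_flim_image(di, objective = "mle", min_counts = 200)
  expect_equal(maps$n_fitted, 100)
  expect_lt(abs(mean(maps$a1) - 0.7), 0.02)
  expect_lt(abs(mean(maps$t2) - 2.5) / 2.5, 0.04)
  expect_equal(dim(maps$a1), c(10, 10))
})

test_that("pixels below the photon floor stay missing; binning rescues them", {
  lo <- uniform_decay_image(frame = 9, counts_per_pixel = 40, seed = 4)
  m1 <- fit_flim_image(lo, binning = 1, min_counts = 200)
  expect_equal(m1$n_fitted, 0)
  expect_true(all(is.na(m1$a1)))
  m3 <- fit_flim_image(lo, binning = 3, min_counts = 200)
  expect_gt(m3$n_fitted, 0)
  expect_gt(sum(!is.na(m3$a1)), sum(!is.na(m1$a1)))
})

test_that("pseudo-color rendering is deterministic with clipped endpoints", {
  m <- matrix(c(0, 0.5, 1, NA), 2, 2)
  out <- render_flim_maps(list(a1 = m), list(a1 = c(0, 1)))
  out2 <- render_flim_maps(list(a1 = m), list(a1 = c(0, 1)))
  expect_identical(out, out2)
  rgb <- out$a1
  expect_equal(rgb[2, 2, ], c(0, 0, 0))                  # missing -> black
  expect_equal(rgb[1, 1, ], c(0, 0, 127) / 255, tolerance = 1e-6)
  expect_equal(rgb[1, 2, ], c(255, 0, 0) / 255, tolerance = 1e-6)
  u <- render_flim_maps(list(a1 = matrix(0.3, 2, 2)), list(a1 = c(0, 1)))$a1
  expect_equal(u[1, 1, ], u[2, 2, ])                     # uniform map
  expect_error(render_flim_maps(list(a1 = m), list(a1 = c(1, 0))), "inverted")
})
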