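test_that("background estimation returns the histogram mode in photon units", {
  expect_equal(estimate_background(array(3, c(4, 4, 2))), 3)
  # ties break toward the smaller value
  expect_equal(estimate_background(array(c(0, 0, 5, 5), c(4, 1, 1))), 0)
  # encoded stacks are decoded first
  vals <- array(0L, c(5, 5, 2)); vals[1:3] <- 64L
  expect_equal(estimate_background(encoded_stack(vals, 4 / 255, 8L)), 0)
  # Poisson background at 0.01 photons/voxel: the mode is 0
  counts <- sample_poisson(array(0.01, c(40, 40, 5)), seed = 2)
  expect_equal(estimate_background(encode_8bit(counts, 4)), 0)
  expect_error(estimate_background(numeric(0)), "empty")
})

test_that("manual background bypasses estimation and is recorded", {
  d <- array(1, c(6, 6, 3))
  kern <- array(0, c(3, 3, 3)); kern[2, 2, 2] <- 1
  psf <- structure(list(values = kern, voxel_pitch = c(1, 1, 1),
                        center = c(2L, 2L, 2L), normalization = "sum_one"),
                   class = "psf_volume")
  fit <- richardson_lucy(d, psf, iterations = 2, background = 0.8)
  expect_equal(fit$background_used, 0.8)
  expect_identical(fit$background_mode, "manual")
  auto <- richardson_lucy(d, psf, iterations = 2, background = "auto")
  expect_equal(auto$background_used, 1)   # constant stack: mode = 1
  expect_identical(auto$background_mode, "auto")
})

test_that("RL with a delta PSF and zero background is the identity from iteration 1", {
  set.seed(4)
  d <- array(rpois(8 * 7 * 4, 3), c(8, 7, 4))
  kern <- array(0, c(3, 3, 3)); kern[2, 2, 2] <- 1
  psf <- structure(list(values = kern, voxel_pitch = c(1, 1, 1),
                        center = c(2L, 2L, 2L), normalization = "sum_one"),
                   class = "psf_volume")
  fit1 <- richardson_lucy(d, psf, iterations = 1, background = 0, support_tol = 0)
  expect_equal(fit1$estimate, d + 0, tolerance = 1e-9)
  fit5 <- richardson_lucy(d, psf, iterations = 5, background = 0, support_tol = 0)
  expect_equal(fit5$estimate, d + 0, tolerance = 1e-9)
})

test_that("RL matches an independently coded iteration on a small phantom", {
  set.seed(9)
  kern <- array(runif(5 * 5 * 3), c(5, 5, 3))
  kern <- kern / sum(kern)
  center <- c(3L, 3L, 2L)
  truth <- array(0, c(12, 11, 5))
  truth[4, 4, 3] <- 20; truth[9, 7, 2] <- 12
  d <- conv_brute(truth, kern, center)
  psf <- structure(list(values = kern, voxel_pitch = c(1, 1, 1),
                        center = center, normalization = "sum_one"),
                   class = "psf_volume")
  for (iters in c(1L, 4L)) {
    fit <- richardson_lucy(d, psf, iterations = iters, background = 0,
                           support_tol = 0)
    expect_equal(fit$estimate, rl_oracle(d, kern, center, iters, b = 0),
                 tolerance = 1e-8)
  }
})

test_that("RMSE to the truth decreases over early iterations on a noiseless phantom", {
  set.seed(10)
  kern <- array(runif(5 * 5 * 3), c(5, 5, 3)); kern <- kern / sum(kern)
  center <- c(3L, 3L, 2L)
  truth <- array(0, c(16, 16, 6))
  truth[5, 5, 3] <- 25; truth[11, 12, 4] <- 18
  d <- conv_brute(truth, kern, center)
  psf <- structure(list(values = kern, voxel_pitch = c(1, 1, 1),
                        center = center, normalization = "sum_one"),
                   class = "psf_volume")
  rmse <- vapply(1:10, function(iters) {
    fit <- richardson_lucy(d, psf, iterations = iters, background = 0,
                           support_tol = 0)
    sqrt(mean((fit$estimate - truth)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("the Poisson log-likelihood trace is non-decreasing and iterates stay finite", {
  pair <- small_psf_pair()
  sim <- simulate_stack(small_sim_config(seed = 6), pair$eff)
  fit <- richardson_lucy(sim$encoded, pair$eff, iterations = 25, background = 0)
  tr <- fit$log_likelihood_trace
  expect_length(tr, 25L)
  expect_true(all(is.finite(tr)))
  expect_true(all(diff(tr) >= -1e-9 * pmax(abs(tr[-1]), 1)))
  expect_true(all(fit$estimate >= 0))
  expect_true(all(is.finite(fit$estimate)))
})

test_that("all-zero observations return a zero estimate without iterating", {
  psf <- small_psf_pair()$eff
  fit <- richardson_lucy(array(0, c(33, 33, 9)), psf, iterations = 10,
                         background = 0)
  expect_equal(sum(fit$estimate), 0)
  expect_identical(fit$iterations_run, 0L)
})

test_that("RL is shift-equivariant for interior content", {
  set.seed(12)
  kern <- array(runif(3 * 3 * 3), c(3, 3, 3)); kern <- kern / sum(kern)
  psf <- structure(list(values = kern, voxel_pitch = c(1, 1, 1),
                        center = c(2L, 2L, 2L), normalization = "sum_one"),
                   class = "psf_volume")
  d <- array(0, c(14, 14, 6))
  d[6:8, 6:8, 3] <- 5
  fit <- richardson_lucy(d, psf, iterations = 6, background = 0, support_tol = 0)
  dshift <- array(0, c(14, 14, 6))
  dshift[7:9, 6:8, 3] <- 5
  fit_s <- richardson_lucy(dshift, psf, iterations = 6, background = 0,
                           support_tol = 0)
  expect_equal(fit_s$estimate[4:12, 4:12, ], fit$estimate[3:11, 4:12, ],
               tolerance = 1e-7)
})

test_that("flux correction matches totals and records the factor", {
  pair <- small_psf_pair()
  sim <- simulate_stack(small_sim_config(seed = 8), pair$eff)
  fit <- richardson_lucy(sim$encoded, pair$eff, iterations = 10, background = 0)
  corr <- flux_correction(fit, sim$encoded)
  target <- sum(pmax(as_photons(sim$encoded), 0))
  expect_equal(sum(corr$estimate), target, tolerance = 1e-9)
  # already-equal totals give a unit factor
  again <- flux_correction(corr, sim$encoded)
  expect_equal(again$flux_scale, corr$flux_scale, tolerance = 1e-12)
  # doubling the target doubles every voxel
  doubled <- flux_correction(fit, as_photons(sim$encoded) * 2, b = 0)
  expect_equal(doubled$estimate, corr$estimate * 2, tolerance = 1e-9)
})

test_that("estimator methods summarize the fit coherently", {
  pair <- small_psf_pair()
  sim <- simulate_stack(small_sim_config(seed = 2), pair$eff)
  fit <- richardson_lucy(sim$encoded, pair$eff, iterations = 8, background = 0)
  s <- summary(fit)
  expect_true(s$monotone)
  expect_equal(s$iterations_run, 8L)
  expect_equal(as.numeric(logLik(fit)), tail(fit$log_likelihood_trace, 1))
  mu <- fitted(fit)
  expect_true(all(mu >= 0))
  r <- residuals(fit, sim$encoded)
  expect_identical(dim(r), dim(mu))
  expect_true(all(is.finite(r)))
  expect_output(print(fit), "Richardson-Lucy")
  expect_output(print(s), "non-decreasing")
})
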