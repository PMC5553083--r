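test_that("default layout is an 8x8 lattice centered in the grid at mid-z", {
  layout <- make_object_layout(sim_config())
  expect_equal(nrow(layout$centers), 64L)
  expect_true(all(layout$centers[, 3] == 21L))       # 0-based slice 20
  expect_equal(range(layout$centers[, 1]), c(31L, 171L))  # 0-based 30..170
  expect_equal(range(layout$centers[, 2]), c(31L, 171L))
  expect_equal(diff(range(layout$centers[, 1])), 140L)
  # consecutive centers differ by exactly the spacing in x or y
  expect_setequal(unique(diff(sort(unique(layout$centers[, 1])))), 20L)
  # all pairwise distances >= spacing (exhaustive enumeration)
  dmat <- as.matrix(stats::dist(layout$centers[, 1:2]))
  expect_gte(min(dmat[upper.tri(dmat)]), 20)
})

test_that("degenerate 1x1 array sits at the grid center and footprints are checked", {
  cfg <- sim_config(array_shape = c(1L, 1L))
  layout <- make_object_layout(cfg)
  expect_equal(nrow(layout$centers), 1L)
  expect_equal(layout$centers[1, ], c(x = 101L, y = 101L, z = 21L))
  expect_error(sim_config(grid_dims = c(100L, 100L, 40L), xy_spacing = 20L,
                          array_shape = c(8L, 8L)), "footprint")
})

test_that("rendering places single-voxel impulses with the requested brightness", {
  cfg <- small_sim_config()
  layout <- make_object_layout(cfg)
  field <- render_objects(layout, brightness = 1)
  expect_equal(sum(field), 9)
  expect_equal(sum(field > 0), 9L)
  # removing one center reduces the total by exactly the brightness
  layout2 <- layout
  layout2$centers <- layout2$centers[-1, , drop = FALSE]
  expect_equal(sum(render_objects(layout2, 1)), 8)
  # empty layout -> all-zero field
  layout0 <- layout
  layout0$centers <- layout0$centers[0, , drop = FALSE]
  expect_equal(sum(render_objects(layout0, 1)), 0)
})

test_that("photon normalization scales to the requested peak and is linear", {
  pair <- small_psf_pair()
  cfg <- small_sim_config()
  field <- convolve_psf(render_objects(make_object_layout(cfg), 1), pair$eff)
  norm1 <- normalize_to_photons(field, 1)
  expect_equal(max(norm1), 1)
  expect_equal(normalize_to_photons(norm1, 1), norm1)     # fixed point
  expect_equal(normalize_to_photons(field, 2), 2 * norm1) # linearity
  expect_error(normalize_to_photons(array(0, c(2, 2, 2)), 1), "positive")
})

test_that("uniform background shifts every voxel by exactly b", {
  set.seed(3)
  field <- array(runif(4 * 4 * 3), c(4, 4, 3))
  out <- add_background(field, 0.01)
  expect_equal(sum(out) - sum(field), 0.01 * length(field))
  expect_equal(min(out), min(field) + 0.01)
  expect_identical(add_background(field, 0), field)
  expect_error(add_background(field, -0.1), "non-negative")
})

test_that("Poisson sampling is reproducible and recovers the mean", {
  zero <- sample_poisson(array(0, c(5, 5, 2)), seed = 99)
  expect_true(all(zero$values == 0L))
  a <- sample_poisson(array(1.3, c(4, 4, 2)), seed = 123)
  b <- sample_poisson(array(1.3, c(4, 4, 2)), seed = 123)
  expect_identical(a$values, b$values)
  # mean recovery: 10,000 draws at mean 1.0 within 3 standard errors
  draws <- sample_poisson(array(1, c(100, 100, 1)), seed = 7)
  expect_lt(abs(mean(draws$values) - 1), 3 * sqrt(1 / 1e4))
  expect_error(sample_poisson(array(-1, c(2, 2, 1)), seed = 1), "non-negative")
})

test_that("8-bit encoding follows the 255-equals-4-photons convention", {
  enc <- encode_8bit(array(c(0, 1, 2, 4), c(4, 1, 1)), photons_full_scale = 4)
  expect_identical(as.vector(enc$values), c(0L, 64L, 128L, 255L))
  expect_equal(enc$photons_per_code, 4 / 255)
  expect_identical(enc$bit_depth, 8L)
  # saturation clips to 255
  expect_identical(as.vector(encode_8bit(array(7, c(1, 1, 1)), 4)$values), 255L)
  # rounding is half away from zero: 0.5/63.75 photons sits exactly at
  # code 0.5 and must round up (banker's rounding would give 0)
  expect_identical(as.vector(encode_8bit(array(0.5 / 63.75, c(1, 1, 1)), 4)$values), 1L)
  expect_identical(photondecon:::round_half_away(c(0.5, 1.5, 2.5, -0.5)),
                   c(1, 2, 3, -1))
})

test_that("expected Poisson stack total matches the average detected image", {
  # Monte-Carlo over 120 seeds on the small grid, within 3 standard errors
  pair <- small_psf_pair()
  cfg <- small_sim_config(background = 0.01)
  layout <- make_object_layout(cfg)
  avg <- add_background(
    normalize_to_photons(convolve_psf(render_objects(layout, 1), pair$eff), 1),
    0.01
  )
  totals <- vapply(1:120, function(s) sum(sample_poisson(avg, s)$values), numeric(1))
  se <- sqrt(sum(avg) / 120)   # var of a Poisson total equals its mean
  expect_lt(abs(mean(totals) - sum(avg)), 3 * se)
})

test_that("simulation runs end to end, also at the finer 40x40x120 nm pitch", {
  pair <- small_psf_pair()
  sim <- simulate_stack(small_sim_config(seed = 5), pair$eff)
  expect_s3_class(sim$encoded, "encoded_stack")
  expect_identical(dim(sim$encoded$values), c(33L, 33L, 9L))
  expect_true(all(sim$counts$values >= 0))
  # same code path at the finer pitch
  cfg_fine <- sim_config(grid_dims = c(33L, 33L, 9L), voxel_pitch = c(40, 40, 120),
                         xy_spacing = 8L, array_shape = c(3L, 3L), seed = 5)
  psf_fine <- effective_confocal_psf(
    born_wolf_psf(optical_params(1.4, 1.5, 488, c(40, 40, 120), c(33L, 33L, 9L))),
    born_wolf_psf(optical_params(1.4, 1.5, 510, c(40, 40, 120), c(33L, 33L, 9L)))
  )
  sim_fine <- simulate_stack(cfg_fine, psf_fine)
  expect_s3_class(sim_fine$encoded, "encoded_stack")
  expect_gt(sum(sim_fine$average_image), 0)
  # identical config and master seed reproduce the stack bit-identically
  sim2 <- simulate_stack(small_sim_config(seed = 5), pair$eff)
  expect_identical(sim$encoded$values, sim2$encoded$values)
})
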