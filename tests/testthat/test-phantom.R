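test_that("the default phantom holds the configured sphere:background contrast", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  expect_identical(max(truth$values) / min(truth$values), 9)
  # sphere-core voxel exactly at sphere activity, far voxel at background
  expect_identical(max(truth$values), 45)
  expect_identical(truth$values[1, 1, 1], 5)
})

test_that("zero-contrast phantom renders uniformly", {
  spec <- phantom_spec(sphere_diameters_mm = c(13, 28),
                       sphere_activity_kBq_ml = 5,
                       background_activity_kBq_ml = 5,
                       field_of_view_mm = c(120, 120, 80),
                       voxel_size_mm = c(4, 4, 4),
                       sphere_centres_mm = list(c(35, 60, 40), c(80, 60, 40)))
  truth <- generate_phantom(spec)
  expect_identical(max(truth$values), min(truth$values))
})

test_that("partial-volume rendering recovers the analytic sphere volume", {
  spec <- phantom_spec(sphere_diameters_mm = 10,
                       field_of_view_mm = c(60, 60, 60),
                       voxel_size_mm = c(1, 1, 1),
                       sphere_centres_mm = list(c(30, 30, 30)))
  truth <- generate_phantom(spec)
  excess <- sum(truth$values - 5) * prod(spec$voxel_size_mm) / 1000  # ml
  analytic <- 40 * (4 / 3) * pi * 0.5^3                              # kBq
  expect_equal(excess, analytic, tolerance = 0.01)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(
    phantom_spec(sphere_diameters_mm = c(20, 30),
                 sphere_centres_mm = list(c(60, 60, 40), c(70, 60, 40)),
                 field_of_view_mm = c(120, 120, 80)),
    "overlap"
  )
  expect_error(
    phantom_spec(sphere_diameters_mm = 30,
                 sphere_centres_mm = list(c(10, 60, 40)),
                 field_of_view_mm = c(120, 120, 80)),
    "field of view"
  )
  expect_error(phantom_spec(sphere_diameters_mm = c(20, 15)),
               "strictly increasing")
  expect_error(phantom_spec(background_activity_kBq_ml = 0), "positive")
})

test_that("an identity acquisition returns the truth unchanged", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  sc <- grid_matched_scanner(spec)
  expect_identical(simulate_scan(truth, sc, seed = 1)$values, truth$values)
})

test_that("blurring bounds the sphere maximum between background and truth", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  sc <- grid_matched_scanner(spec, psf = 8)
  img <- simulate_scan(truth, sc, seed = 1)
  expect_lt(max(img$values), 45)
  expect_gt(max(img$values), 5)
})

test_that("acquisition is deterministic under a fixed seed", {
  spec <- small_phantom_spec(voxel = 4)
  truth <- generate_phantom(spec)
  sc <- grid_matched_scanner(spec, psf = 6, noise = 0.05)
  a <- simulate_scan(truth, sc, seed = 42)
  b <- simulate_scan(truth, sc, seed = 42)
  c <- simulate_scan(truth, sc, seed = 43)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("sphere maxima decrease monotonically with total blur", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  maxima <- vapply(c(3, 5, 8, 12), function(f) {
    max(simulate_scan(truth, grid_matched_scanner(spec, psf = f), 1)$values)
  }, numeric(1))
  expect_true(all(diff(maxima) <= 0))
})

test_that("a blur-only acquisition conserves total activity to 0.1%", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  img <- simulate_scan(truth, grid_matched_scanner(spec, psf = 7), 1)
  expect_equal(sum(img$values) / sum(truth$values), 1, tolerance = 1e-3)
})

test_that("resolution-recovery overshoot inflates sphere maxima", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  plain <- simulate_scan(truth, grid_matched_scanner(spec, psf = 5, post = 4), 1)
  rr <- simulate_scan(truth,
                      grid_matched_scanner(spec, psf = 5, post = 4, rr = 1), 1)
  expect_gt(max(rr$values), max(plain$values))
  expect_true(all(rr$values >= 0))
})
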