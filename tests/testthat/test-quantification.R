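test_that("unblurred truth gives unit recovery for every sphere", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  prof <- recovery_coefficients(truth, sphere_vois(spec), 45, scanner = "T")
  expect_true(all(prof$rc_max == 1))
  expect_identical(prof$n_replicates, rep(1L, 2))
})

test_that("a uniform zero-contrast image has RC 1 everywhere", {
  spec <- small_phantom_spec(voxel = 2)
  flat <- volume_image(array(5, dim(generate_phantom(spec)$values)),
                       spec$voxel_size_mm)
  prof <- recovery_coefficients(flat, sphere_vois(spec), 5)
  expect_true(all(prof$rc_max == 1))
})

test_that("recovery loss grows as spheres shrink and blur widens", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  profs <- lapply(c(5, 8, 11), function(f) {
    img <- simulate_scan(truth, grid_matched_scanner(spec, psf = f), 1)
    recovery_coefficients(img, sphere_vois(spec), 45)
  })
  for (p in profs) {
    expect_true(all(p$rc_max <= 1))
    expect_true(all(diff(p$rc_max) >= 0))     # non-decreasing in diameter
  }
  rc_by_blur <- sapply(profs, function(p) p$rc_max)
  expect_true(all(apply(rc_by_blur, 1, diff) < 0))  # decreasing in blur
})

test_that("recovery_coefficients validates VOIs and activity", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  vois <- sphere_vois(spec)
  expect_error(recovery_coefficients(truth, vois, 0), "positive")
  bad <- vois
  bad$cx_mm[1] <- -5
  expect_error(recovery_coefficients(truth, bad, 45), "outside")
})

test_that("average_profiles is the per-sphere mean and is permutation invariant", {
  base <- tibble::tibble(scanner = "A", reconstruction = "no_RR",
                         diameter_mm = c(10, 20), rc_max = c(0.8, 0.9),
                         n_replicates = 1L)
  p1 <- base
  p2 <- dplyr::mutate(base, rc_max = c(0.9, 1.0))
  p3 <- dplyr::mutate(base, rc_max = c(1.0, 1.1))
  avg <- average_profiles(list(p1, p2, p3))
  expect_equal(avg$rc_max, c(0.9, 1.0))
  expect_identical(avg$n_replicates, c(3L, 3L))
  expect_equal(average_profiles(list(p3, p1, p2)), avg)
  expect_equal(average_profiles(list(p1, p1, p1))$rc_max, p1$rc_max)
  p_bad <- dplyr::mutate(base, diameter_mm = c(10, 25))
  expect_error(average_profiles(list(p1, p_bad)), "sphere set")
})

test_that("replicate-mean RC converges on the noise-free value", {
  spec <- small_phantom_spec(voxel = 4)
  truth <- generate_phantom(spec)
  vois <- sphere_vois(spec)
  quiet <- grid_matched_scanner(spec, psf = 7)
  noisy <- grid_matched_scanner(spec, psf = 7, noise = 0.05)
  rc0 <- recovery_coefficients(simulate_scan(truth, quiet, 1), vois, 45)$rc_max
  reps <- lapply(1:30, function(s) {
    recovery_coefficients(simulate_scan(truth, noisy, s), vois, 45)$rc_max
  })
  mat <- do.call(rbind, reps)
  rc_sd <- apply(mat, 2, sd)
  # the max picks up a positive noise bias, so centre on the MC mean and
  # check a fresh 3-replicate mean stays within 3 sd/sqrt(3) of it
  mc_mean <- colMeans(mat)
  fresh <- colMeans(do.call(rbind, lapply(31:33, function(s) {
    recovery_coefficients(simulate_scan(truth, noisy, s), vois, 45)$rc_max
  })))
  expect_true(all(abs(fresh - mc_mean) < 3 * rc_sd / sqrt(3) + 1e-9))
  # and the noise-free value is approached from above by less than 3 sd
  expect_true(all(mc_mean - rc0 >= 0))
  expect_true(all(mc_mean - rc0 < 3 * rc_sd))
})

test_that("lesion_suv_max is the patch maximum with unit checks", {
  flat <- volume_image(array(1, c(4, 4, 4)), c(2, 2, 2), units = "SUV")
  expect_identical(lesion_suv_max(flat), 1)
  lesion <- petharm:::lesion_truth_patch(14, 10, voxel_mm = 2)
  expect_identical(lesion_suv_max(lesion), 10)
  blurred <- apply_gaussian(lesion, 8)
  expect_gt(lesion_suv_max(blurred), 1)
  expect_lt(lesion_suv_max(blurred), 10)
  kbq <- volume_image(array(1, c(4, 4, 4)), c(2, 2, 2), units = "kBq_ml")
  expect_error(lesion_suv_max(kbq), "SUV")
})

test_that("RC tables round-trip through CSV", {
  prof <- tibble::tibble(scanner = "A", reconstruction = "RR",
                         diameter_mm = c(10, 37), rc_max = c(0.61, 1.02),
                         n_replicates = 3L)
  path <- tempfile(fileext = ".csv")
  write_rc_profile(prof, path)
  back <- read_rc_profile(path)
  expect_equal(as.data.frame(back), as.data.frame(prof))
  unlink(path)
})
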