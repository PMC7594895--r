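test_that("cross-scanner windows scale the reference window exactly", {
  earl_like <- band_table(data.frame(diameter_mm = 10, nominal = 1,
                                     lower = 0.9, upper = 1.1))
  target <- tibble::tibble(scanner = "B", reconstruction = "no_RR",
                           diameter_mm = 10, rc_max = 0.8, n_replicates = 3L)
  derived <- derive_cross_scanner_bands(earl_like, target)
  expect_equal(derived$nominal, 0.8)
  expect_equal(derived$lower, 0.72)
  expect_equal(derived$upper, 0.88)
  expect_identical(attr(derived, "source"), "derived")
  expect_identical(attr(derived, "reference_scanner"), "B")

  # identity when the target profile equals the reference nominals
  earl <- earl_band_table()
  prof <- tibble::tibble(scanner = "E", reconstruction = "no_RR",
                         diameter_mm = earl$diameter_mm,
                         rc_max = earl$nominal, n_replicates = 1L)
  same <- derive_cross_scanner_bands(earl, prof)
  expect_equal(same$lower, earl$lower)
  expect_equal(same$upper, earl$upper)

  # relative window widths preserved exactly for an arbitrary profile
  prof2 <- dplyr::mutate(prof, rc_max = c(0.5, 0.63, 0.8, 0.88, 0.93, 0.97))
  d2 <- derive_cross_scanner_bands(earl, prof2)
  expect_equal(d2$upper / d2$nominal, earl$upper / earl$nominal,
               tolerance = 1e-14)
  expect_equal(d2$lower / d2$nominal, earl$lower / earl$nominal,
               tolerance = 1e-14)

  expect_error(derive_cross_scanner_bands(earl, target), "sphere set")
})

test_that("band tables validate their intervals", {
  expect_error(band_table(data.frame(diameter_mm = 10, nominal = 1,
                                     lower = 1.05, upper = 1.1)), "lower")
  expect_error(band_table(data.frame(diameter_mm = 10, nominal = 1)),
               "columns")
})

test_that("compliance uses closed intervals and limit-relative deviations", {
  bands <- band_table(data.frame(diameter_mm = c(10, 20),
                                 nominal = c(0.8, 1.0),
                                 lower = c(0.72, 0.9),
                                 upper = c(0.9, 1.1)))
  at_limit <- tibble::tibble(scanner = "S", reconstruction = "no_RR",
                             diameter_mm = c(10, 20), rc_max = c(0.72, 1.1),
                             n_replicates = 1L)
  rep1 <- check_compliance(at_limit, bands)
  expect_true(all(rep1$in_band))
  expect_true(all_pass(rep1))
  expect_true(all(rep1$deviation_pct == 0))

  low <- dplyr::mutate(at_limit, rc_max = c(0.716, 1.0))
  rep2 <- check_compliance(low, bands)
  expect_false(rep2$in_band[1])
  expect_equal(rep2$deviation_pct[1], -100 * (0.72 - 0.716) / 0.72,
               tolerance = 1e-12)
  expect_equal(abs(rep2$deviation_pct[1]), 0.5556, tolerance = 1e-3)
  expect_false(all_pass(rep2))

  nominal <- dplyr::mutate(at_limit, rc_max = c(0.8, 1.0))
  rep3 <- check_compliance(nominal, bands)
  expect_true(all_pass(rep3))
  expect_true(all(rep3$deviation_pct == 0))
})

test_that("an already compliant protocol needs no smoothing", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  vois <- sphere_vois(spec)
  img <- simulate_scan(truth, grid_matched_scanner(spec, psf = 6), 1)
  prof <- recovery_coefficients(img, vois, 45)
  bands <- tight_bands_from_profile(prof, rel_width = 0.05)
  flt <- optimise_filter(list(img), vois, 45, bands, search_max_mm = 8)
  expect_identical(flt$fwhm_mm, 0)
  expect_identical(flt$residual, 0)
  expect_true(flt$all_pass)
})

test_that("the optimiser recovers the Gaussian resolution-matching width", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  vois <- sphere_vois(spec)
  src <- simulate_scan(truth, grid_matched_scanner(spec, psf = 3), 1)
  ref <- simulate_scan(truth, grid_matched_scanner(spec, psf = 5), 1)
  # only 13 and 28 mm spheres here, so a very tight window is needed for
  # band entry to coincide with the closed form
  bands <- tight_bands_from_profile(recovery_coefficients(ref, vois, 45),
                                    rel_width = 0.005)
  flt <- optimise_filter(list(src), vois, 45, bands, search_max_mm = 8)
  expect_equal(flt$fwhm_mm, sqrt(5^2 - 3^2), tolerance = 0.3 / 4)
  expect_identical(flt$residual, 0)
  expect_true(flt$all_pass)
})

test_that("an RR protocol needs positive smoothing to meet no-RR bands", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  vois <- sphere_vois(spec)
  norr <- simulate_scan(truth, grid_matched_scanner(spec, psf = 5, post = 4), 1)
  rr <- simulate_scan(truth,
                      grid_matched_scanner(spec, psf = 5, post = 4, rr = 1), 1)
  bands <- tight_bands_from_profile(recovery_coefficients(norr, vois, 45),
                                    rel_width = 0.05)
  flt <- optimise_filter(list(rr), vois, 45, bands, search_max_mm = 10)
  expect_gt(flt$fwhm_mm, 0)
  expect_true(flt$all_pass)
  expect_true(all_pass(check_compliance(flt$rc_profile, bands)))
})

test_that("the band objective is unimodal in the kernel width", {
  spec <- small_phantom_spec(voxel = 2)
  truth <- generate_phantom(spec)
  vois <- sphere_vois(spec)
  src <- simulate_scan(truth, grid_matched_scanner(spec, psf = 4), 1)
  ref <- simulate_scan(truth, grid_matched_scanner(spec, psf = 8), 1)
  bands <- tight_bands_from_profile(recovery_coefficients(ref, vois, 45),
                                    rel_width = 0.01)
  flt <- optimise_filter(list(src), vois, 45, bands, search_max_mm = 12)
  path <- flt$search[order(flt$search$fwhm_mm), ]
  sgn <- sign(diff(path$objective))
  sgn <- sgn[sgn != 0]
  expect_lte(sum(diff(sgn) != 0), 1)   # falls, then rises
})

test_that("harmonising lesions only ever lowers SUVmax", {
  sc <- default_scanners(noise_sd_fraction = 0)
  coh <- generate_cohort(c(lung = 3), sc["A_noRR"], seed = 5)
  same <- harmonise_lesions(coh, 0)
  expect_equal(same$suv_max_harmonised, same$suv_max_raw)
  sm <- harmonise_lesions(coh, 6)
  expect_true(all(sm$suv_max_harmonised <= sm$suv_max_raw))
  expect_true(all(sm$suv_max_harmonised > 0))
  broken <- coh
  broken$lesion_patch[2] <- list(NULL)
  expect_error(harmonise_lesions(broken, 5), broken$patient_id[2])
})
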