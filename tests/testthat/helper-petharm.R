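# Shared fixtures: everything is generated in code at test time.

# compact two-sphere phantom on a coarse grid for fast unit tests
small_phantom_spec <- function(voxel = 2) {
  phantom_spec(
    sphere_diameters_mm = c(13, 28),
    field_of_view_mm = c(120, 120, 80),
    voxel_size_mm = rep(voxel, 3),
    sphere_centres_mm = list(c(35, 60, 40), c(80, 60, 40))
  )
}

# scanner whose output grid matches the truth grid of `spec`
grid_matched_scanner <- function(spec, name = "S", psf = 0, post = 0,
                                 noise = 0, rr = 0) {
  scanner_profile(
    name, psf, post,
    matrix_size = as.integer(round(spec$field_of_view_mm[1:2] /
                                     spec$voxel_size_mm[1:2])),
    slice_thickness_mm = spec$voxel_size_mm[3],
    transaxial_fov_mm = spec$field_of_view_mm[1],
    noise_sd_fraction = noise,
    rr_overshoot = rr
  )
}

# random interior embedded in a constant border wide enough that edge
# padding is exact for the kernels used in the tests
bordered_random_volume <- function(n = 80, border = 27, base = 1,
                                   amplitude = 9, voxel = 1, seed = 1) {
  withr::with_seed(seed, {
    vals <- array(base, rep(n, 3))
    core <- (border + 1):(n - border)
    vals[core, core, core] <- base + amplitude * runif(length(core)^3)
    volume_image(vals, rep(voxel, 3))
  })
}

# acceptance window of +/- rel_width around a measured RC profile; used to
# validate resolution matching, where a tight window makes band entry
# coincide with the Gaussian closed form
tight_bands_from_profile <- function(profile, rel_width = 0.02) {
  band_table(data.frame(
    diameter_mm = profile$diameter_mm,
    nominal = profile$rc_max,
    lower = profile$rc_max * (1 - rel_width),
    upper = profile$rc_max * (1 + rel_width)
  ))
}
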