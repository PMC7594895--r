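#' Measure per-sphere recovery coefficients
#'
#' For each sphere VOI, the maximum-voxel recovery coefficient
#' `RC_max = max(voxels within the search region) / true_sphere_activity`.
#' The search region is a sphere of radius `diameter/2 + blur_margin_mm`
#' centred on the known sphere centre, so the maximum survives blurring and
#' modest resampling shifts. RC_max is the sole recovery metric used here:
#' SUVmax is the clinical quantity being harmonised, and maximum-based
#' recovery is what a Gaussian harmonisation kernel acts on.
#'
#' @param image a [volume_image()] in kBq/ml.
#' @param vois tibble of sphere VOIs as returned by [sphere_vois()]
#'   (`diameter_mm`, `cx_mm`, `cy_mm`, `cz_mm`).
#' @param true_sphere_activity true filled sphere activity (kBq/ml).
#' @param blur_margin_mm search-region margin added to the sphere radius.
#' @param scanner,reconstruction provenance labels carried into the output.
#' @return An `rc_profile`: a tibble with columns `scanner`,
#'   `reconstruction`, `diameter_mm`, `rc_max`, `n_replicates`.
#' @examples
#' spec <- phantom_spec(voxel_size_mm = c(4, 4, 4))
#' truth <- generate_phantom(spec)
#' recovery_coefficients(truth, sphere_vois(spec), 45)
#' @export
recovery_coefficients <- function(image, vois, true_sphere_activity,
                                  blur_margin_mm = 10,
                                  scanner = NA_character_,
                                  reconstruction = "no_RR") {
  stopifnot(inherits(image, "volume_image"))
  if (true_sphere_activity <= 0) abort("`true_sphere_activity` must be positive")
  extent <- volume_extent_mm(image)
  rc <- purrr::pmap_dbl(vois, function(diameter_mm, cx_mm, cy_mm, cz_mm, ...) {
    cen <- c(cx_mm, cy_mm, cz_mm)
    r_sphere <- diameter_mm / 2
    if (any(cen - r_sphere < 0) || any(cen + r_sphere > extent)) {
      abort(sprintf("VOI (%.0f mm sphere) lies outside the image extent", diameter_mm))
    }
    r <- r_sphere + blur_margin_mm
    max(voxels_within_radius(image, cen, r))
  })
  new_rc_profile(tibble(
    scanner = scanner,
    reconstruction = reconstruction,
    diameter_mm = vois$diameter_mm,
    rc_max = rc / true_sphere_activity,
    n_replicates = 1L
  ))
}

new_rc_profile <- function(x) {
  class(x) <- c("rc_profile", class(x))
  x
}

# values of voxels whose centres lie within `radius` of `centre` (mm),
# clipped to the grid
voxels_within_radius <- function(image, centre, radius) {
  dims <- dim(image$values)
  v <- image$voxel_size_mm
  rng <- lapply(1:3, function(a) {
    ax <- (seq_len(dims[a]) - 0.5) * v[a]
    which(abs(ax - centre[a]) <= radius)
  })
  if (any(lengths(rng) == 0)) abort("search region contains no voxels")
  dx <- (rng[[1]] - 0.5) * v[1] - centre[1]
  dy <- (rng[[2]] - 0.5) * v[2] - centre[2]
  dz <- (rng[[3]] - 0.5) * v[3] - centre[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  block <- image$values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  block[d2 <= radius^2]
}

#' Average recovery-coefficient profiles over replicate scans
#'
#' Per-sphere arithmetic mean of `rc_max` across replicate profiles that
#' share the scanner, reconstruction and sphere set; `n_replicates`
#' accumulates the replicate counts of the inputs. Averaging precedes any
#' band comparison, mirroring the usual multi-scan accreditation protocol.
#'
#' @param profiles list of `rc_profile` tibbles from
#'   [recovery_coefficients()].
#' @return A single averaged `rc_profile`.
#' @examples
#' p <- tibble::tibble(scanner = "A", reconstruction = "no_RR",
#'                     diameter_mm = c(10, 37), rc_max = c(0.5, 1),
#'                     n_replicates = 1L)
#' average_profiles(list(p, p, p))
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) abort("`profiles` must be a non-empty list")
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(sort(p$diameter_mm), sort(ref$diameter_mm))) {
      abort("profiles do not share the same sphere set")
    }
    if (!identical(unique(p$scanner), unique(ref$scanner)) ||
        !identical(unique(p$reconstruction), unique(ref$reconstruction))) {
      abort("profiles do not share scanner and reconstruction")
    }
  }
  out <- dplyr::bind_rows(profiles) |>
    dplyr::group_by(.data$scanner, .data$reconstruction, .data$diameter_mm) |>
    dplyr::summarise(rc_max = mean(.data$rc_max),
                     n_replicates = sum(.data$n_replicates),
                     .groups = "drop") |>
    dplyr::arrange(.data$diameter_mm)
  new_rc_profile(out)
}

#' Maximum SUV of a lesion patch
#'
#' @param patch a [volume_image()] in SUV units.
#' @return The maximum voxel value (SUVmax).
#' @export
lesion_suv_max <- function(patch) {
  stopifnot(inherits(patch, "volume_image"))
  if (patch$units != "SUV") abort("`patch` must be in SUV units")
  if (length(patch$values) == 0L) abort("`patch` is empty")
  max(patch$values)
}

#' Write / read recovery-coefficient tables as CSV
#'
#' @param profile an `rc_profile` tibble.
#' @param path CSV file path.
#' @return `write_rc_profile()` returns `path` invisibly; `read_rc_profile()`
#'   returns an `rc_profile` tibble.
#' @export
write_rc_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rc_profile
#' @export
read_rc_profile <- function(path) {
  new_rc_profile(as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)))
}
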