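#' Create a 3D image volume
#'
#' A `volume_image` is the carrier object for all image operations in
#' petharm: a 3D array of voxel values together with the voxel spacing, the
#' world-coordinate origin and the value units. Voxel indices are 0-based
#' conceptually, with the centre of voxel `(i, j, k)` at
#' `origin + (index + 0.5) * voxel_size` in mm.
#'
#' @param values 3D numeric array of voxel values, all finite.
#' @param voxel_size_mm positive numeric length-3 vector, voxel edge lengths
#'   in mm (x, y, z).
#' @param origin_mm numeric length-3 vector, world position of the volume's
#'   corner in mm.
#' @param units `"kBq_ml"` for activity concentration or `"SUV"` for
#'   dimensionless standardised uptake values.
#' @return An object of class `volume_image`.
#' @examples
#' vol <- volume_image(array(1, c(4, 4, 4)), voxel_size_mm = c(2, 2, 2))
#' dim(vol$values)
#' @export
volume_image <- function(values, voxel_size_mm, origin_mm = c(0, 0, 0),
                         units = c("kBq_ml", "SUV")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array")
  }
  if (!all(is.finite(values))) abort("all voxel values must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 3 positive lengths")
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) abort("`origin_mm` must have length 3")
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm,
         origin_mm = origin_mm, units = units),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels of %s mm [%s]\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 4), collapse = " x "), x$units))
  cat(sprintf("  value range: %.4g .. %.4g\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.array.volume_image <- function(x, ...) x$values

# physical extent of the volume in mm per axis
volume_extent_mm <- function(vol) dim(vol$values) * vol$voxel_size_mm

#' Apply an isotropic 3D Gaussian smoothing filter
#'
#' Convolves a volume with a normalised Gaussian kernel of the given full
#' width at half maximum in mm (`sigma = fwhm / (2 * sqrt(2 * log(2)))`).
#' The kernel is isotropic in world (mm) space; anisotropic voxels get a
#' per-axis sigma in voxel units. Convolution is separable with replicate
#' edge padding and a kernel truncated at 6 sigma then renormalised, so the
#' kernel is nonnegative and sums to one: no local maximum can increase and
#' a flat region is left exactly unchanged.
#'
#' @param image a [volume_image()].
#' @param fwhm_mm nonnegative kernel width in mm; `0` returns the image
#'   unchanged.
#' @param truncate kernel support radius in sigmas (default 6).
#' @return The smoothed [volume_image()].
#' @examples
#' vol <- volume_image(array(rnorm(8^3, 10), c(8, 8, 8)), c(2, 2, 2))
#' sm <- apply_gaussian(vol, fwhm_mm = 5)
#' max(sm$values) <= max(vol$values)
#' @export
apply_gaussian <- function(image, fwhm_mm, truncate = 6) {
  stopifnot(inherits(image, "volume_image"))
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0) {
    abort("`fwhm_mm` must be a single nonnegative number")
  }
  if (fwhm_mm == 0) return(image)
  sigma_vox <- (fwhm_mm / fwhm_sigma_ratio) / image$voxel_size_mm
  kernels <- lapply(sigma_vox, gaussian_kernel_1d, truncate = truncate)
  vals <- sepconv3_cpp(image$values, dim(image$values), kernels)
  volume_image(vals, image$voxel_size_mm, image$origin_mm, image$units)
}

# sampled, truncated, renormalised 1D Gaussian kernel (sigma in voxels)
gaussian_kernel_1d <- function(sigma_vox, truncate = 6) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Resample a volume to a new voxel grid
#'
#' Trilinear interpolation onto a grid with the given voxel spacing that
#' covers the same physical extent (origin preserved). Sampling positions
#' outside the source grid are clamped to the nearest voxel centre, which
#' continues the edge value.
#'
#' @param vol a [volume_image()].
#' @param new_voxel_size_mm positive length-3 voxel spacing of the target
#'   grid in mm.
#' @return A [volume_image()] on the new grid.
#' @export
resample_volume <- function(vol, new_voxel_size_mm) {
  stopifnot(inherits(vol, "volume_image"))
  new_voxel_size_mm <- as.numeric(new_voxel_size_mm)
  if (length(new_voxel_size_mm) != 3L || any(new_voxel_size_mm <= 0)) {
    abort("`new_voxel_size_mm` must be 3 positive lengths")
  }
  old_v <- vol$voxel_size_mm
  dims <- dim(vol$values)
  extent <- dims * old_v
  new_dims <- pmax(1L, as.integer(round(extent / new_voxel_size_mm)))
  if (all(abs(new_voxel_size_mm - old_v) < 1e-9) && all(new_dims == dims)) {
    return(vol)
  }

  ax <- lapply(1:3, function(a) {
    if (dims[a] == 1L) {
      n <- new_dims[a]
      return(list(i0 = rep(1L, n), i1 = rep(1L, n), w = rep(0, n)))
    }
    pos <- (seq_len(new_dims[a]) - 0.5) * new_voxel_size_mm[a]
    xi <- pos / old_v[a] - 0.5              # 0-based fractional voxel index
    xi <- pmin(pmax(xi, 0), dims[a] - 1)
    i0 <- pmin(floor(xi), dims[a] - 2)
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(i0) + 2L, w = xi - i0)
  })

  out <- array(0, new_dims)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) ax[[1]]$i1 else ax[[1]]$i0
    iy <- if (cy) ax[[2]]$i1 else ax[[2]]$i0
    iz <- if (cz) ax[[3]]$i1 else ax[[3]]$i0
    wx <- if (cx) ax[[1]]$w else 1 - ax[[1]]$w
    wy <- if (cy) ax[[2]]$w else 1 - ax[[2]]$w
    wz <- if (cz) ax[[3]]$w else 1 - ax[[3]]$w
    w <- outer(outer(wx, wy), wz)
    out <- out + vol$values[ix, iy, iz, drop = FALSE] * w
  }
  volume_image(out, new_voxel_size_mm, vol$origin_mm, vol$units)
}

#' Read and write volumes as NIfTI-1
#'
#' `write_volume()` stores a [volume_image()] as a `.nii` / `.nii.gz` file
#' with the voxel spacing in the pixdim header; `read_volume()` reads one
#' back. NIfTI does not carry the petharm unit flag, so the units must be
#' stated on read.
#'
#' @param vol a [volume_image()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param units units to assign to the volume read from `path`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [volume_image()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, units = c("kBq_ml", "SUV")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  volume_image(vals, RNifti::pixdim(img)[1:3], units = units)
}
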