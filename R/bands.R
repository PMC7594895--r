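#' Recovery-coefficient acceptance band tables
#'
#' A band table holds, per sphere diameter, a nominal recovery coefficient
#' and a closed acceptance interval `[lower, upper]` (boundary values
#' pass). `band_table()` builds one from a data frame;
#' `earl_band_table()` loads the EARL-style maximum-voxel RC specification
#' shipped with the package as an editable YAML asset
#' (`inst/extdata/earl_rc_max_bands.yaml`).
#'
#' @param per_sphere data frame with columns `diameter_mm`, `nominal`,
#'   `lower`, `upper` (all positive, `lower < nominal < upper`).
#' @param source `"EARL"`, `"derived"` or `"custom"`.
#' @param reference_scanner identifier of the scanner a derived table was
#'   transferred from, if any.
#' @return A `band_table` tibble with attributes `source` and
#'   `reference_scanner`.
#' @examples
#' earl_band_table()
#' @export
band_table <- function(per_sphere, source = "custom",
                       reference_scanner = NA_character_) {
  x <- as_tibble(per_sphere)
  need <- c("diameter_mm", "nominal", "lower", "upper")
  if (!all(need %in% names(x))) {
    abort("`per_sphere` needs columns diameter_mm, nominal, lower, upper")
  }
  x <- dplyr::arrange(x[need], .data$diameter_mm)
  if (any(x$lower <= 0) || any(x$lower >= x$nominal) || any(x$nominal >= x$upper)) {
    abort("each sphere needs 0 < lower < nominal < upper")
  }
  structure(x, source = source, reference_scanner = reference_scanner,
            class = c("band_table", class(x)))
}

#' @rdname band_table
#' @param path YAML file describing the band table; defaults to the
#'   packaged EARL-style asset.
#' @export
earl_band_table <- function(path = system.file("extdata",
                                               "earl_rc_max_bands.yaml",
                                               package = "petharm")) {
  spec <- yaml::read_yaml(path)
  per_sphere <- dplyr::bind_rows(lapply(spec$bands, as_tibble))
  band_table(per_sphere, source = spec$source %||% "EARL")
}

#' Transfer an acceptance window to a second scanner
#'
#' When harmonising one scanner to another there is no published acceptance
#' range, so the reference window's *relative* width is borrowed: for each
#' sphere the target scanner's mean RC becomes the nominal value and the
#' limits are scaled by the reference table's `lower/nominal` and
#' `upper/nominal` ratios. Relative window widths are therefore preserved
#' exactly.
#'
#' @param reference_bands a [band_table()] supplying the relative widths
#'   (typically the EARL table).
#' @param target_profile an `rc_profile` of the target scanner (usually a
#'   replicate average), sharing the sphere set of `reference_bands`.
#' @return A derived [band_table()] with `reference_scanner` set.
#' @examples
#' bt <- band_table(data.frame(diameter_mm = 10, nominal = 1,
#'                             lower = 0.9, upper = 1.1))
#' prof <- tibble::tibble(scanner = "B", reconstruction = "no_RR",
#'                        diameter_mm = 10, rc_max = 0.8, n_replicates = 1L)
#' derive_cross_scanner_bands(bt, prof)
#' @export
derive_cross_scanner_bands <- function(reference_bands, target_profile) {
  stopifnot(inherits(reference_bands, "band_table"))
  if (!setequal(reference_bands$diameter_mm, target_profile$diameter_mm)) {
    abort("band table and target profile do not share the same sphere set")
  }
  joined <- dplyr::inner_join(
    as_tibble(reference_bands),
    as_tibble(target_profile)[c("diameter_mm", "rc_max")],
    by = "diameter_mm"
  )
  band_table(
    tibble(diameter_mm = joined$diameter_mm,
           nominal = joined$rc_max,
           lower = joined$rc_max * joined$lower / joined$nominal,
           upper = joined$rc_max * joined$upper / joined$nominal),
    source = "derived",
    reference_scanner = unique(target_profile$scanner)[1]
  )
}

#' Check a recovery-coefficient profile against an acceptance band table
#'
#' Each sphere's RC is flagged in/out of its closed acceptance interval.
#' For violations the deviation beyond the nearest violated limit is
#' reported as a signed percentage of that limit
#' (`100 * (rc - limit) / limit`; negative below the lower limit, positive
#' above the upper limit, 0 inside the band).
#'
#' @param profile an `rc_profile` (typically a replicate average).
#' @param bands a [band_table()] covering the same sphere set.
#' @return A `compliance_report` tibble with columns `diameter_mm`,
#'   `rc_max`, `lower`, `nominal`, `upper`, `in_band`, `deviation_pct`, and
#'   attribute `all_pass`.
#' @examples
#' bt <- band_table(data.frame(diameter_mm = 10, nominal = 1,
#'                             lower = 0.72, upper = 1.1))
#' prof <- tibble::tibble(scanner = "A", reconstruction = "no_RR",
#'                        diameter_mm = 10, rc_max = 0.716, n_replicates = 1L)
#' check_compliance(prof, bt)  # 0.56% below the lower limit
#' @export
check_compliance <- function(profile, bands) {
  stopifnot(inherits(bands, "band_table"))
  if (!setequal(profile$diameter_mm, bands$diameter_mm)) {
    abort("profile and band table do not share the same sphere set")
  }
  x <- dplyr::inner_join(
    as_tibble(profile)[c("diameter_mm", "rc_max")],
    as_tibble(bands), by = "diameter_mm"
  ) |>
    dplyr::arrange(.data$diameter_mm) |>
    dplyr::mutate(
      in_band = .data$rc_max >= .data$lower & .data$rc_max <= .data$upper,
      deviation_pct = dplyr::case_when(
        .data$rc_max < .data$lower ~ 100 * (.data$rc_max - .data$lower) / .data$lower,
        .data$rc_max > .data$upper ~ 100 * (.data$rc_max - .data$upper) / .data$upper,
        TRUE ~ 0
      )
    )
  x <- x[c("diameter_mm", "rc_max", "lower", "nominal", "upper",
           "in_band", "deviation_pct")]
  structure(x, all_pass = all(x$in_band),
            class = c("compliance_report", class(x)))
}

#' @rdname check_compliance
#' @param report a `compliance_report`.
#' @export
all_pass <- function(report) isTRUE(attr(report, "all_pass"))

#' Harmonise lesion SUVmax records with a Gaussian kernel
#'
#' Applies the harmonisation filter to each record's reconstructed lesion
#' patch and records the new patch maximum in `suv_max_harmonised`; the raw
#' value is untouched. Smoothing with a normalised Gaussian can only lower
#' a maximum, so `suv_max_harmonised <= suv_max_raw` always.
#'
#' @param records lesion cohort tibble from [generate_cohort()] (must carry
#'   the `lesion_patch` list-column).
#' @param filter a `harmonisation_filter` from [optimise_filter()], or a
#'   single nonnegative FWHM in mm.
#' @return The records tibble with `suv_max_harmonised` filled in.
#' @export
harmonise_lesions <- function(records, filter) {
  fwhm <- if (inherits(filter, "harmonisation_filter")) filter$fwhm_mm else filter
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm < 0) {
    abort("`filter` must be a harmonisation_filter or a nonnegative FWHM")
  }
  if (!"lesion_patch" %in% names(records)) {
    abort("`records` has no `lesion_patch` column")
  }
  missing <- purrr::map_lgl(records$lesion_patch, is.null)
  if (any(missing)) {
    abort(sprintf("record(s) without a lesion patch: %s",
                  paste(records$patient_id[missing], collapse = ", ")))
  }
  records$suv_max_harmonised <- purrr::map_dbl(
    records$lesion_patch,
    function(p) lesion_suv_max(apply_gaussian(p, fwhm))
  )
  records
}
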