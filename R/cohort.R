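#' Default lesion population model
#'
#' Log-normal lesion diameters (median 20 mm) and log-normal true lesion
#' uptake (median SUV 8), chosen so that simulated SUVmax spans roughly
#' 2-25 across scanners and lesion sizes. These are stated modelling
#' assumptions for the synthetic cohorts, not values estimated from any
#' patient data.
#'
#' @param diameter_meanlog,diameter_sdlog log-normal parameters of the
#'   lesion diameter (mm).
#' @param uptake_meanlog,uptake_sdlog log-normal parameters of the true
#'   lesion uptake (SUV) over a background of SUV 1.
#' @return A named list of distribution parameters.
#' @export
lesion_model <- function(diameter_meanlog = log(20), diameter_sdlog = 0.35,
                         uptake_meanlog = log(8), uptake_sdlog = 0.45) {
  list(diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
       uptake_meanlog = uptake_meanlog, uptake_sdlog = uptake_sdlog)
}

default_site_counts <- function() {
  c(head_neck = 10L, lung = 10L, oesophagus = 5L, colorectum = 8L,
    lymphoma = 7L)
}

# render a spherical lesion of given diameter/uptake on a background of
# SUV 1, centred in a cubic patch
lesion_truth_patch <- function(diameter_mm, uptake_suv, voxel_mm = 2,
                               margin_mm = 20, supersample = 4L) {
  extent <- diameter_mm + 2 * margin_mm
  n <- max(3L, as.integer(ceiling(extent / voxel_mm)))
  cen <- rep(n * voxel_mm / 2, 3)
  vals <- render_spheres(rep(n, 3L), rep(voxel_mm, 3L), list(cen),
                         diameter_mm / 2, uptake_suv, background = 1,
                         supersample = supersample)
  volume_image(vals, rep(voxel_mm, 3L), units = "SUV")
}

#' Generate a synthetic lesion cohort
#'
#' Draws per-patient lesion diameters and uptakes from the population
#' model, renders each lesion as a hot sphere on a background of SUV 1,
#' and acquires it through the assigned scanner profile(s) with
#' [simulate_scan()]. Unpaired mode gives every scanner its own cohort
#' with the requested per-site counts. Paired mode (`paired_rr = TRUE`)
#' takes exactly two profiles differing in their RR setting and produces
#' two records per patient (reconstructions `RR` and `no_RR`) from the
#' same ground-truth patch and the same noise realisation, emulating a
#' pair of reconstructions of the same raw data.
#'
#' @param n_per_site named integer vector of patients per disease site.
#' @param scanners list of [scanner_profile()]s (non-empty); exactly two
#'   for `paired_rr`.
#' @param model population model from [lesion_model()].
#' @param paired_rr produce paired RR / no-RR records per patient.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param patch_voxel_mm ground-truth patch voxel size.
#' @param patch_margin_mm background margin around the lesion.
#' @return A tibble with one row per record: `patient_id`, `site`,
#'   `scanner`, `reconstruction`, `lesion_diameter_mm`, `true_uptake_suv`,
#'   `suv_max_raw`, `suv_max_harmonised` (NA until [harmonise_lesions()]),
#'   and the list-column `lesion_patch` of reconstructed [volume_image()]
#'   patches.
#' @examples
#' sc <- default_scanners(noise_sd_fraction = 0)
#' coh <- generate_cohort(c(lung = 2), sc["B"], seed = 1)
#' coh[c("patient_id", "site", "suv_max_raw")]
#' @export
generate_cohort <- function(n_per_site = default_site_counts(),
                            scanners,
                            model = lesion_model(),
                            paired_rr = FALSE,
                            seed = 1L,
                            patch_voxel_mm = 2,
                            patch_margin_mm = 20) {
  if (!length(scanners)) abort("`scanners` must be a non-empty list")
  if (any(n_per_site <= 0)) abort("site counts must be positive")
  scanners <- if (inherits(scanners, "scanner_profile")) list(scanners) else scanners
  if (paired_rr && length(scanners) != 2L) {
    abort("`paired_rr` needs exactly two scanner profiles (RR and no-RR)")
  }

  sites <- rep(names(n_per_site), times = n_per_site)
  n_pat <- length(sites)
  n_groups <- if (paired_rr) 1L else length(scanners)

  draws <- withr::with_seed(as.integer(seed), {
    list(
      diameter = rlnorm(n_pat * n_groups, model$diameter_meanlog,
                        model$diameter_sdlog),
      uptake = rlnorm(n_pat * n_groups, model$uptake_meanlog,
                      model$uptake_sdlog),
      noise_seed = sample.int(.Machine$integer.max - 1L, n_pat * n_groups)
    )
  })

  recon_label <- function(sc) if (sc$rr_overshoot > 0) "RR" else "no_RR"

  rows <- list()
  k <- 0L
  for (g in seq_len(n_groups)) {
    for (p in seq_len(n_pat)) {
      k <- k + 1L
      truth <- lesion_truth_patch(draws$diameter[k], draws$uptake[k],
                                  patch_voxel_mm, patch_margin_mm)
      scs <- if (paired_rr) scanners else scanners[g]
      pid <- if (paired_rr) sprintf("P%03d", p) else
        sprintf("%s-%03d", scs[[1]]$name, p)
      for (sc in scs) {
        patch <- simulate_scan(truth, sc, seed = draws$noise_seed[k])
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = pid,
          site = sites[p],
          scanner = sc$name,
          reconstruction = recon_label(sc),
          lesion_diameter_mm = draws$diameter[k],
          true_uptake_suv = draws$uptake[k],
          suv_max_raw = lesion_suv_max(patch),
          suv_max_harmonised = NA_real_,
          lesion_patch = list(patch)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a lesion cohort as CSV
#'
#' The image patches are not serialised; the CSV holds the record table
#' (`patient_id`, `site`, `scanner`, `reconstruction`,
#' `lesion_diameter_mm`, `suv_max_raw`, `suv_max_harmonised`).
#'
#' @param records cohort tibble from [generate_cohort()].
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   record tibble.
#' @export
write_cohort <- function(records, path) {
  keep <- c("patient_id", "site", "scanner", "reconstruction",
            "lesion_diameter_mm", "suv_max_raw", "suv_max_harmonised")
  utils::write.csv(as.data.frame(records[keep]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
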