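#' Build the default study configuration
#'
#' Bundles everything a full harmonisation study needs: the phantom
#' specification, the virtual scanner profiles, the number of replicate
#' phantom scans per protocol (3, the usual accreditation practice), the
#' target band table, the harmonisation pairs, the clinical cohort layout
#' (two 40-patient cohorts with fixed site counts plus a 10-patient paired
#' RR/no-RR subset) and the master seed. Every derived seed is a fixed
#' offset of `seed`, so a config reproduces its outputs bit for bit.
#'
#' @param seed master integer seed.
#' @param phantom a [phantom_spec()].
#' @param scanners named list of [scanner_profile()]s.
#' @param replicates phantom scans per protocol.
#' @param bands target [band_table()] (EARL-style by default).
#' @param pairs list of `list(source =, target =)` harmonisation pairs;
#'   `target` is either `"EARL"` (the configured band table) or the name
#'   of a scanner whose replicate-mean RCs define a derived window.
#' @param cohort list describing the clinical stage: `n_per_site`,
#'   `main_scanners` (one 40-patient cohort each), `paired_scanners`
#'   (RR/no-RR pair), `paired_n_per_site`, `model` ([lesion_model()]).
#' @param search_max_mm optimiser search range.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 20200602,
                         phantom = phantom_spec(),
                         scanners = default_scanners(),
                         replicates = 3L,
                         bands = earl_band_table(),
                         pairs = list(
                           list(source = "A_RR", target = "EARL"),
                           list(source = "A_noRR", target = "EARL"),
                           list(source = "B", target = "EARL"),
                           list(source = "A_RR", target = "B")
                         ),
                         cohort = list(
                           n_per_site = default_site_counts(),
                           main_scanners = c("A_RR", "B"),
                           paired_scanners = c("A_RR", "A_noRR"),
                           paired_n_per_site = c(head_neck = 1L, lung = 5L,
                                                 lymphoma = 4L),
                           model = lesion_model()
                         ),
                         search_max_mm = 12) {
  cfg <- structure(
    list(seed = as.integer(seed), phantom = phantom, scanners = scanners,
         replicates = as.integer(replicates), bands = bands, pairs = pairs,
         cohort = cohort, search_max_mm = search_max_mm),
    class = "study_config"
  )
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  nm <- names(cfg$scanners)
  if (is.null(nm) || any(nm == "")) abort("`scanners` must be a named list")
  for (p in cfg$pairs) {
    if (!p$source %in% nm) {
      abort(sprintf("harmonisation pair names unknown scanner '%s'", p$source))
    }
    if (!identical(p$target, "EARL") && !p$target %in% nm) {
      abort(sprintf("harmonisation target '%s' is neither 'EARL' nor a scanner",
                    p$target))
    }
  }
  ch <- cfg$cohort
  for (s in c(ch$main_scanners, ch$paired_scanners)) {
    if (!s %in% nm) abort(sprintf("cohort references unknown scanner '%s'", s))
  }
  if (cfg$replicates < 1L) abort("`replicates` must be >= 1")
  invisible(cfg)
}

#' Read a study configuration from YAML
#'
#' Maps a YAML document onto [study_config()]. Recognised top-level keys
#' are `seed`, `replicates`, `search_max_mm`, `phantom` (arguments of
#' [phantom_spec()]), `scanners` (named maps of [scanner_profile()]
#' arguments), `bands` (path to a band YAML, as for [earl_band_table()]),
#' `pairs` (list of `{source, target}`) and `cohort`. Omitted keys keep
#' the package defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$replicates)) args$replicates <- y$replicates
  if (!is.null(y$search_max_mm)) args$search_max_mm <- y$search_max_mm
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$scanners)) {
    args$scanners <- lapply(names(y$scanners), function(nm) {
      do.call(scanner_profile, c(list(name = nm), y$scanners[[nm]]))
    })
    names(args$scanners) <- names(y$scanners)
  }
  if (!is.null(y$bands)) args$bands <- earl_band_table(y$bands)
  if (!is.null(y$pairs)) args$pairs <- y$pairs
  if (!is.null(y$cohort)) {
    cohort <- utils::modifyList(formals(study_config)$cohort |> eval(),
                                y$cohort)
    cohort$n_per_site <- unlist(cohort$n_per_site)
    cohort$paired_n_per_site <- unlist(cohort$paired_n_per_site)
    args$cohort <- cohort
  }
  do.call(study_config, args)
}

#' Phantom stage: replicate scans, recovery coefficients, filters
#'
#' Simulates the configured number of replicate phantom acquisitions for
#' every scanner/protocol, measures and averages recovery coefficients,
#' derives cross-scanner acceptance windows where the target is a scanner,
#' optimises the harmonisation kernel for every configured pair, and
#' reports pre- and post-harmonisation compliance. Deterministic under the
#' config seed.
#'
#' @param config a [study_config()].
#' @return A `phantom_stage` list: `filters` (one row per pair: `source`,
#'   `target`, `fwhm_mm`, `residual`, `all_pass`), `filter_objects`,
#'   `rc_profiles` (replicate means), `replicate_images`, `compliance_pre`
#'   and `compliance_post` (per pair), `bands_used`.
#' @export
run_phantom_stage <- function(config) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  truth <- generate_phantom(config$phantom)
  vois <- sphere_vois(config$phantom)
  act <- config$phantom$sphere_activity_kBq_ml

  scanners_needed <- unique(c(
    vapply(config$pairs, `[[`, "", "source"),
    setdiff(vapply(config$pairs, `[[`, "", "target"), "EARL")
  ))

  replicate_images <- list()
  rc_profiles <- list()
  for (nm in scanners_needed) {
    sc <- config$scanners[[nm]]
    reps <- lapply(seq_len(config$replicates), function(k) {
      simulate_scan(truth, sc, seed = config$seed + 1000L * match(nm, scanners_needed) + k)
    })
    profs <- lapply(reps, recovery_coefficients, vois = vois,
                    true_sphere_activity = act, scanner = nm,
                    reconstruction = if (sc$rr_overshoot > 0) "RR" else "no_RR")
    replicate_images[[nm]] <- reps
    rc_profiles[[nm]] <- average_profiles(profs)
  }

  filters <- list()
  compliance_pre <- list()
  compliance_post <- list()
  bands_used <- list()
  for (p in config$pairs) {
    key <- paste(p$source, p$target, sep = "->")
    bands <- if (identical(p$target, "EARL")) {
      config$bands
    } else {
      derive_cross_scanner_bands(config$bands, rc_profiles[[p$target]])
    }
    bands_used[[key]] <- bands
    compliance_pre[[key]] <- check_compliance(rc_profiles[[p$source]], bands)
    flt <- optimise_filter(replicate_images[[p$source]], vois, act, bands,
                           search_max_mm = config$search_max_mm,
                           source_protocol = p$source, target = p$target)
    filters[[key]] <- flt
    compliance_post[[key]] <- flt$compliance
  }

  structure(
    list(
      filters = dplyr::bind_rows(lapply(filters, function(f) {
        tibble(source = f$source_protocol, target = f$target,
               fwhm_mm = f$fwhm_mm, residual = f$residual,
               all_pass = f$all_pass)
      })),
      filter_objects = filters,
      rc_profiles = dplyr::bind_rows(rc_profiles),
      replicate_images = replicate_images,
      compliance_pre = compliance_pre,
      compliance_post = compliance_post,
      bands_used = bands_used
    ),
    class = "phantom_stage"
  )
}

#' Clinical stage: synthetic cohorts, harmonised SUVmax, statistics
#'
#' Generates the two 40-patient cohorts (one per main scanner) and the
#' 10-patient paired RR/no-RR subset, harmonises lesion SUVmax per
#' configured arm, and runs the statistical battery: the five-arm one-way
#' ANOVA over the main cohorts (raw and harmonised arms), the four-arm
#' ANOVA over the paired subset, ratio Bland-Altman of RR vs no-RR SUVmax
#' before and after harmonisation, and the corresponding straight-line
#' fits. A Shapiro-Wilk/log10 gate is applied to the pooled SUVmax of each
#' design before its ANOVA.
#'
#' @param config a [study_config()].
#' @param filters filter table from [run_phantom_stage()] (the `filters`
#'   tibble or the `phantom_stage` itself).
#' @return A `clinical_stage` list: `arms_main` and `arms_paired` (long
#'   tibbles of arm vs SUVmax), `anova_main`, `anova_paired`,
#'   `bland_altman` (`raw`, `harmonised`), `fits` (`raw`, `harmonised`),
#'   `cohorts`.
#' @export
run_clinical_stage <- function(config, filters) {
  stopifnot(inherits(config, "study_config"))
  if (inherits(filters, "phantom_stage")) filters <- filters$filters
  filter_for <- function(source, target) {
    row <- filters[filters$source == source & filters$target == target, ]
    if (!nrow(row)) {
      abort(sprintf("no filter available for arm %s->%s", source, target))
    }
    row$fwhm_mm[1]
  }
  ch <- config$cohort

  # --- main 40+40 cohorts -------------------------------------------------
  main <- purrr::imap(
    setNames(ch$main_scanners, ch$main_scanners),
    function(nm, i) {
      generate_cohort(ch$n_per_site, config$scanners[nm], model = ch$model,
                      seed = config$seed + 71L * match(nm, ch$main_scanners))
    }
  )
  arm <- function(records, label, fwhm = NULL) {
    suv <- if (is.null(fwhm)) records$suv_max_raw else
      harmonise_lesions(records, fwhm)$suv_max_harmonised
    tibble(arm = label, patient_id = records$patient_id, suv_max = suv)
  }
  nm1 <- ch$main_scanners[1]; nm2 <- ch$main_scanners[2]
  a_rr <- main[[nm1]]
  b <- main[[nm2]]
  arms_main <- dplyr::bind_rows(
    arm(a_rr, nm1),
    arm(a_rr, paste0(nm1, "->EARL"), filter_for(nm1, "EARL")),
    arm(a_rr, paste0(nm1, "->", nm2), filter_for(nm1, nm2)),
    arm(b, nm2),
    arm(b, paste0(nm2, "->EARL"), filter_for(nm2, "EARL"))
  )
  anova_main <- one_way_anova(arms_main, suv_max, arm, log10_gate = TRUE)

  # --- paired RR / no-RR subset ------------------------------------------
  paired <- generate_cohort(ch$paired_n_per_site,
                            config$scanners[ch$paired_scanners],
                            model = ch$model, paired_rr = TRUE,
                            seed = config$seed + 997L)
  rr <- paired[paired$reconstruction == "RR", ]
  norr <- paired[paired$reconstruction == "no_RR", ]
  rr_name <- unique(rr$scanner)
  norr_name <- unique(norr$scanner)
  rr_h <- harmonise_lesions(rr, filter_for(rr_name, "EARL"))
  norr_h <- harmonise_lesions(norr, filter_for(norr_name, "EARL"))

  arms_paired <- dplyr::bind_rows(
    arm(rr, "RR"),
    arm(rr_h, "RR->EARL", NULL) |>
      dplyr::mutate(suv_max = rr_h$suv_max_harmonised),
    arm(norr, "no_RR"),
    arm(norr_h, "no_RR->EARL", NULL) |>
      dplyr::mutate(suv_max = norr_h$suv_max_harmonised)
  )
  anova_paired <- one_way_anova(arms_paired, suv_max, arm, log10_gate = TRUE)

  ba_raw <- bland_altman_ratio(numerator = rr$suv_max_raw,
                               denominator = norr$suv_max_raw)
  ba_harm <- bland_altman_ratio(numerator = rr_h$suv_max_harmonised,
                                denominator = norr_h$suv_max_harmonised)
  fit_raw <- linear_fit(x = rr$suv_max_raw, y = norr$suv_max_raw)
  fit_harm <- linear_fit(x = rr_h$suv_max_harmonised,
                         y = norr_h$suv_max_harmonised)

  structure(
    list(arms_main = arms_main, arms_paired = arms_paired,
         anova_main = anova_main, anova_paired = anova_paired,
         bland_altman = list(raw = ba_raw, harmonised = ba_harm),
         fits = list(raw = fit_raw, harmonised = fit_harm),
         cohorts = list(main = main, paired = paired)),
    class = "clinical_stage"
  )
}

#' Run the full harmonisation study
#'
#' [run_phantom_stage()] followed by [run_clinical_stage()], wrapped into
#' a study report with provenance (seed, config hash, package version).
#'
#' @param config a [study_config()].
#' @return A `study_report` list: `filters`, `phantom`, `clinical`,
#'   `provenance`.
#' @export
run_study <- function(config = study_config()) {
  phantom <- run_phantom_stage(config)
  clinical <- run_clinical_stage(config, phantom)
  structure(
    list(filters = phantom$filters, phantom = phantom, clinical = clinical,
         provenance = list(
           seed = config$seed,
           config_hash = rlang::hash(config),
           package_version = as.character(utils::packageVersion("petharm"))
         )),
    class = "study_report"
  )
}

#' Write a study report to disk
#'
#' Emits the auditable text outputs of a study: the filter table, the
#' replicate-mean RC profiles, per-pair pre/post compliance tables and the
#' cohort record tables as CSV; the statistics summary and provenance as
#' JSON; and a short Markdown overview. Figures are intentionally
#' regenerated from these CSVs via the `plot_*()` functions rather than
#' stored.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$filters),
                   file.path(dir, "filters.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$phantom$rc_profiles),
                   file.path(dir, "rc_profiles.csv"), row.names = FALSE)
  comp <- dplyr::bind_rows(
    purrr::imap(report$phantom$compliance_pre,
                ~ dplyr::mutate(as_tibble(.x), pair = .y, stage = "pre")),
    purrr::imap(report$phantom$compliance_post,
                ~ dplyr::mutate(as_tibble(.x), pair = .y, stage = "post"))
  )
  utils::write.csv(as.data.frame(comp), file.path(dir, "compliance.csv"),
                   row.names = FALSE)
  for (nm in names(report$clinical$cohorts$main)) {
    write_cohort(report$clinical$cohorts$main[[nm]],
                 file.path(dir, sprintf("cohort_%s.csv", nm)))
  }
  write_cohort(report$clinical$cohorts$paired,
               file.path(dir, "cohort_paired.csv"))

  stats <- list(
    anova_main = as.list(glance(report$clinical$anova_main)),
    anova_paired = as.list(glance(report$clinical$anova_paired)),
    bland_altman = list(
      raw = as.list(glance(report$clinical$bland_altman$raw)),
      harmonised = as.list(glance(report$clinical$bland_altman$harmonised))
    ),
    fits = list(
      raw = as.list(glance(report$clinical$fits$raw)),
      harmonised = as.list(glance(report$clinical$fits$harmonised))
    ),
    provenance = report$provenance
  )
  jsonlite::write_json(stats, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA)

  md <- c(
    "# SUV harmonisation study report",
    "",
    sprintf("Seed: %d; config hash: %s; petharm %s",
            report$provenance$seed, report$provenance$config_hash,
            report$provenance$package_version),
    "",
    "## Harmonisation filters (FWHM, mm)",
    "",
    paste(utils::capture.output(print(as.data.frame(report$filters))),
          collapse = "\n"),
    "",
    "## Statistics",
    "",
    sprintf("- Main cohorts: F(%d,%d) = %.3g, p = %.3g",
            report$clinical$anova_main$df_between,
            report$clinical$anova_main$df_within,
            report$clinical$anova_main$f_stat,
            report$clinical$anova_main$p_value),
    sprintf("- Paired subset: F(%d,%d) = %.3g, p = %.3g",
            report$clinical$anova_paired$df_between,
            report$clinical$anova_paired$df_within,
            report$clinical$anova_paired$f_stat,
            report$clinical$anova_paired$p_value),
    sprintf("- RR/no-RR mean SUVmax ratio: %.3g raw, %.3g harmonised",
            report$clinical$bland_altman$raw$mean_ratio,
            report$clinical$bland_altman$harmonised$mean_ratio),
    sprintf("- no-RR vs RR slope: %.3g raw, %.3g harmonised",
            report$clinical$fits$raw$slope,
            report$clinical$fits$harmonised$slope)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
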