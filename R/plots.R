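#' Plot recovery coefficients against an acceptance window
#'
#' RC vs sphere diameter for one or more profiles, with the band table's
#' acceptance window drawn as a ribbon and its nominal curve dashed.
#'
#' @param profiles an `rc_profile` tibble (profiles are distinguished by
#'   their `scanner`/`reconstruction` columns).
#' @param bands a [band_table()].
#' @return A ggplot object.
#' @export
plot_rc_bands <- function(profiles, bands) {
  bands_tbl <- as_tibble(bands)
  profs <- as_tibble(profiles) |>
    dplyr::mutate(profile = paste(.data$scanner, .data$reconstruction))
  ggplot2::ggplot(bands_tbl, ggplot2::aes(x = .data$diameter_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$nominal), linetype = "dashed") +
    ggplot2::geom_line(data = profs,
                       ggplot2::aes(y = .data$rc_max, colour = .data$profile)) +
    ggplot2::geom_point(data = profs,
                        ggplot2::aes(y = .data$rc_max, colour = .data$profile)) +
    ggplot2::labs(x = "Sphere diameter (mm)",
                  y = expression(RC[max]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_ratio, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Pair mean SUVmax", y = "SUVmax ratio") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of SUVmax distributions by arm
#'
#' @param arms long tibble with columns `arm` and `suv_max` (as produced
#'   by [run_clinical_stage()]).
#' @return A ggplot object.
#' @export
plot_suv_distributions <- function(arms) {
  ggplot2::ggplot(arms, ggplot2::aes(x = .data$arm, y = .data$suv_max)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = expression(SUV[max])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @method autoplot compliance_report
#' @export
autoplot.compliance_report <- function(object, ...) {
  x <- as_tibble(object)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$diameter_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$nominal), linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rc_max,
                                     colour = .data$in_band)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "Sphere diameter (mm)", y = expression(RC[max]),
                  colour = "In band") +
    ggplot2::theme_minimal()
}
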