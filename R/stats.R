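#' Shapiro-Wilk normality gate with log10 fallback
#'
#' Tests the raw values for normality (Shapiro-Wilk); when normality is
#' rejected at `alpha` the values are log10-transformed, which is the
#' conventional pre-step before parametric comparison of SUVmax
#' distributions. W and p refer to the raw-scale test either way.
#'
#' @param values positive numeric vector, length >= 3, non-constant.
#' @param alpha rejection level for the gate (default 0.05).
#' @return List with `values` (possibly transformed), `log10_transformed`,
#'   `W`, `p_value`.
#' @examples
#' g <- normality_gate(exp(rnorm(50)))
#' g$log10_transformed
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3L) abort("need at least 3 values")
  if (sd(values) == 0) abort("values are constant; normality is undefined")
  sw <- shapiro.test(values)
  transform <- sw$p.value < alpha
  if (transform && any(values <= 0)) {
    abort("log10 transform requested for non-positive values")
  }
  list(values = if (transform) log10(values) else values,
       log10_transformed = transform,
       W = unname(sw$statistic),
       p_value = sw$p.value)
}

#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA across groups of a data frame, with an optional
#' Shapiro-Wilk/log10 gate applied to the pooled response first (the usual
#' SUVmax workflow). Degrees of freedom are `groups - 1` and `N - groups`.
#'
#' @param data data frame in long format.
#' @param value unquoted column with the response.
#' @param group unquoted column with the group labels.
#' @param log10_gate apply [normality_gate()] to the pooled response before
#'   fitting.
#' @param gate_alpha alpha for the gate.
#' @return An object of class `anova_oneway` with fields `f_stat`,
#'   `df_between`, `df_within`, `p_value`, `log10_transformed`, and the
#'   underlying [stats::aov()] fit; has [tidy()] and [glance()] methods.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
#' glance(one_way_anova(df, y, g))  # F = 1.5
#' @export
one_way_anova <- function(data, value, group, log10_gate = FALSE,
                          gate_alpha = 0.05) {
  value <- enquo(value); group <- enquo(group)
  y <- dplyr::pull(data, !!value)
  g <- factor(dplyr::pull(data, !!group))
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  if (any(table(g) < 2L)) abort("every group needs at least 2 observations")
  gated <- FALSE
  gate <- NULL
  if (log10_gate) {
    gate <- normality_gate(y, alpha = gate_alpha)
    y <- gate$values
    gated <- gate$log10_transformed
  }
  fit <- aov(y ~ g, data = data.frame(y = y, g = g))
  s <- summary(fit)[[1]]
  structure(
    list(f_stat = s[["F value"]][1],
         df_between = as.integer(s[["Df"]][1]),
         df_within = as.integer(s[["Df"]][2]),
         p_value = s[["Pr(>F)"]][1],
         log10_transformed = gated,
         gate = gate,
         fit = fit),
    class = "anova_oneway"
  )
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%d,%d) = %.3g, p = %.3g\n",
              if (x$log10_transformed) " (log10 SUVmax)" else "",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' @method tidy anova_oneway
#' @export
tidy.anova_oneway <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble(term = trimws(rownames(s)), df = s[["Df"]],
         sumsq = s[["Sum Sq"]], meansq = s[["Mean Sq"]],
         statistic = s[["F value"]], p.value = s[["Pr(>F)"]])
}

#' @method glance anova_oneway
#' @export
glance.anova_oneway <- function(x, ...) {
  tibble(f_stat = x$f_stat, df_between = x$df_between,
         df_within = x$df_within, p_value = x$p_value,
         log10_transformed = x$log10_transformed)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired observations, with the standard
#' conventions made explicit: zero differences are dropped; the exact
#' distribution is used for n <= 25 effective pairs without ties in the
#' absolute differences, otherwise the normal approximation with
#' continuity and tie correction; if every difference is zero the test is
#' degenerate and p = 1 is returned by convention.
#'
#' Note that pairing only has its usual interpretation for genuinely
#' paired measurements; applying it to two independent cohorts (as is
#' sometimes done for demographic tables) answers a different question.
#'
#' @param paired_a,paired_b numeric vectors of equal length >= 5.
#' @return List with `statistic` (V), `p_value`, `n_effective`, `exact`.
#' @examples
#' wilcoxon_signed_rank(1:6, c(2, 1, 5, 3, 7, 9))$p_value
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) abort("inputs must have equal length")
  if (length(paired_a) < 5L) abort("need at least 5 pairs")
  d <- paired_b - paired_a
  d <- d[d != 0]
  if (!length(d)) {
    return(list(statistic = NA_real_, p_value = 1, n_effective = 0L,
                exact = TRUE))
  }
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25L && !ties
  res <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_effective = length(d), exact = exact)
}

#' Ratio Bland-Altman agreement analysis
#'
#' Agreement between two positive paired measurements via their per-pair
#' ratio: reports the mean ratio, its sd, the limits of agreement
#' `mean +/- 1.96 sd`, the number of ratios beyond `mean +/- 2 sd`, and
#' the Pearson correlation of the ratio against the pair mean (a
#' magnitude-dependence check). The "95% CI about the mean" language often
#' used with this plot refers to these limits of agreement.
#'
#' @param data optional data frame; when supplied, `numerator` and
#'   `denominator` are unquoted column names, otherwise numeric vectors.
#' @param numerator,denominator positive paired measurements.
#' @return A `bland_altman` object with `mean_ratio`, `sd_ratio`,
#'   `loa_lower`, `loa_upper`, `n_outliers`, `pearson_r_vs_mean`, `n`, and
#'   the per-pair table `data`; has [glance()] and [autoplot()] methods.
#' @examples
#' ba <- bland_altman_ratio(numerator = c(1, 1.2, 1.4) * 5,
#'                          denominator = c(5, 5, 5))
#' glance(ba)
#' @export
bland_altman_ratio <- function(data = NULL, numerator, denominator) {
  if (!is.null(data)) {
    num <- dplyr::pull(data, {{ numerator }})
    den <- dplyr::pull(data, {{ denominator }})
  } else {
    num <- numerator; den <- denominator
  }
  if (length(num) != length(den)) abort("inputs must have equal length")
  if (length(num) < 2L) abort("need at least 2 pairs")
  if (any(den == 0)) abort("denominator contains zeros")
  ratio <- num / den
  m <- mean(ratio)
  s <- sd(ratio)
  pair_mean <- (num + den) / 2
  r <- if (s == 0 || sd(pair_mean) == 0) NA_real_ else cor(ratio, pair_mean)
  structure(
    list(mean_ratio = m, sd_ratio = s,
         loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
         n_outliers = sum(ratio < m - 2 * s | ratio > m + 2 * s),
         pearson_r_vs_mean = r,
         n = length(ratio),
         data = tibble(numerator = num, denominator = den,
                       ratio = ratio, pair_mean = pair_mean)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Ratio Bland-Altman (n = %d): mean %.3g, LoA %.3g-%.3g, %d outlier(s), r vs mean %.2g\n",
    x$n, x$mean_ratio, x$loa_lower, x$loa_upper, x$n_outliers,
    x$pearson_r_vs_mean))
  invisible(x)
}

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(mean_ratio = x$mean_ratio, sd_ratio = x$sd_ratio,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         n_outliers = x$n_outliers, pearson_r_vs_mean = x$pearson_r_vs_mean,
         n = x$n)
}

#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning slope, intercept and r
#' squared, for the SUVmax-vs-SUVmax regression comparisons.
#'
#' @param data optional data frame; when supplied, `x` and `y` are
#'   unquoted column names, otherwise numeric vectors.
#' @param x,y paired observations (`x` non-constant).
#' @return A `linear_fit` object (`slope`, `intercept`, `r_squared`,
#'   `fit`); has [tidy()] and [glance()] methods.
#' @examples
#' glance(linear_fit(x = 0:2, y = c(1, 3, 5)))  # slope 2, intercept 1
#' @export
linear_fit <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    xv <- dplyr::pull(data, {{ x }})
    yv <- dplyr::pull(data, {{ y }})
  } else {
    xv <- x; yv <- y
  }
  if (length(xv) != length(yv)) abort("inputs must have equal length")
  if (length(xv) < 2L) abort("need at least 2 points")
  if (sd(xv) == 0) abort("`x` is constant; slope undefined")
  fit <- lm(yv ~ xv)
  # summary.lm warns on an exactly collinear fit; r^2 = 1 is still the answer
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2,
         fit = fit),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.3g x + %.3g (r^2 = %.3g)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(term = c("intercept", "slope"), estimate = s[, 1],
         std_error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared)
}
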