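test_that("the normality gate passes normal data and transforms log-normal data", {
  x_norm <- withr::with_seed(11, rnorm(50, 10, 1))
  g1 <- normality_gate(x_norm)
  expect_false(g1$log10_transformed)
  expect_identical(g1$values, x_norm)
  expect_true(g1$p_value >= 0 && g1$p_value <= 1)

  # strongly skewed data should be flagged in essentially every realisation
  flags <- vapply(1:40, function(s) {
    normality_gate(withr::with_seed(s, rlnorm(50, 0, 1)))$log10_transformed
  }, logical(1))
  expect_gte(mean(flags), 0.95)

  expect_error(normality_gate(rep(2, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
  res <- one_way_anova(df, y, g)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 4L)
  expect_equal(res$f_stat, 1.5, tolerance = 1e-12)

  ident <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  res0 <- one_way_anova(ident, y, g)
  expect_equal(res0$f_stat, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)

  big <- data.frame(g = rep(letters[1:5], each = 40),
                    y = withr::with_seed(1, rnorm(200)))
  res5 <- one_way_anova(big, y, g)
  expect_identical(c(res5$df_between, res5$df_within), c(4L, 195L))

  gl <- glance(res)
  expect_s3_class(gl, "tbl_df")
  expect_identical(gl$f_stat, res$f_stat)
  td <- tidy(res)
  expect_identical(nrow(td), 2L)

  expect_error(one_way_anova(data.frame(g = "a", y = 1), y, g), "2 groups")
  expect_error(
    one_way_anova(data.frame(g = c("a", "a", "b"), y = 1:3), y, g),
    "at least 2 observations"
  )
})

test_that("the signed-rank p matches brute-force sign enumeration at n = 6", {
  a <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  b <- c(2.1, 1.3, 5.2, 3.6, 8.0, 5.1)
  d <- b - a
  res <- wilcoxon_signed_rank(a, b)
  expect_true(res$exact)

  # enumerate all 2^6 sign assignments of the ranked |d|
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- as.vector(signs %*% rk)
  p_exact <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("signed-rank conventions: zeros dropped, ties approximated, extremes detected", {
  same <- c(1, 2, 3, 4, 5)
  expect_identical(wilcoxon_signed_rank(same, same)$p_value, 1)
  a <- withr::with_seed(3, runif(20, 1, 5))
  expect_lt(wilcoxon_signed_rank(a, a + 10)$p_value, 0.01)
  tied <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
  expect_false(tied$exact)
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
  expect_error(wilcoxon_signed_rank(1:5, 1:6), "equal length")
  expect_error(wilcoxon_signed_rank(1:4, 2:5), "at least 5")
})

test_that("ratio Bland-Altman matches hand arithmetic", {
  ba <- bland_altman_ratio(numerator = c(1.0, 1.2, 1.4) * 7,
                           denominator = rep(7, 3))
  expect_equal(ba$mean_ratio, 1.2, tolerance = 1e-12)
  expect_equal(ba$sd_ratio, 0.2, tolerance = 1e-12)
  expect_equal(ba$loa_lower, 1.2 - 1.96 * 0.2, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1.2 + 1.96 * 0.2, tolerance = 1e-12)
  expect_identical(ba$n_outliers, 0L)

  ident <- bland_altman_ratio(numerator = c(2, 3, 4), denominator = c(2, 3, 4))
  expect_equal(ident$mean_ratio, 1, tolerance = 1e-12)
  expect_equal(ident$sd_ratio, 0, tolerance = 1e-12)
  expect_identical(ident$n_outliers, 0L)

  expect_error(bland_altman_ratio(numerator = 1:3, denominator = c(1, 0, 2)),
               "zero")
  # data-frame-first form agrees with the vector form
  df <- data.frame(rr = c(5, 6, 8), norr = c(4, 5.5, 7))
  expect_equal(glance(bland_altman_ratio(df, rr, norr)),
               glance(bland_altman_ratio(numerator = df$rr,
                                         denominator = df$norr)))
})

test_that("limits of agreement cover ~95% of log-normal ratio data", {
  coverage <- vapply(1:100, function(s) {
    r <- withr::with_seed(s, rlnorm(10, log(1.15), 0.1))
    ba <- bland_altman_ratio(numerator = r * 5, denominator = rep(5, 10))
    mean(r >= ba$loa_lower & r <= ba$loa_upper)
  }, numeric(1))
  expect_gte(mean(coverage), 0.95)
})

test_that("linear_fit reproduces exact and sampled lines", {
  f1 <- linear_fit(x = c(0, 1, 2), y = c(0, 1, 2))
  expect_equal(glance(f1), tibble::tibble(slope = 1, intercept = 0,
                                          r_squared = 1), tolerance = 1e-12)
  f2 <- linear_fit(x = c(0, 1, 2), y = c(1, 3, 5))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)

  xy <- withr::with_seed(8, {
    x <- runif(100, 0, 10)
    list(x = x, y = 2.5 * x + 1 + rnorm(100, sd = 0.5))
  })
  f3 <- linear_fit(x = xy$x, y = xy$y)
  se <- tidy(f3)$std_error[2]
  expect_lt(abs(f3$slope - 2.5), 3 * se)

  # order invariance and r^2 invariance under affine rescaling of y
  ord <- withr::with_seed(9, sample(100))
  f4 <- linear_fit(x = xy$x[ord], y = xy$y[ord])
  expect_equal(f4$slope, f3$slope, tolerance = 1e-12)
  f5 <- linear_fit(x = xy$x, y = 3 * xy$y + 7)
  expect_equal(f5$r_squared, f3$r_squared, tolerance = 1e-12)

  expect_error(linear_fit(x = rep(1, 5), y = 1:5), "constant")
})
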