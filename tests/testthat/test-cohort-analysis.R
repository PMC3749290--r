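test_that("identical groups show no difference; separated groups show p < 0.001", {
  set.seed(70)
  same <- data.frame(group = rep(c("CF", "control"), each = 20),
                     EI = rep(rnorm(20, 5, 1), 2))
  res <- compare_groups(same, "EI")
  expect_gt(res$p_value, 0.9)
  expect_equal(res$summaries$CF$mean, res$summaries$control$mean)

  # means 3+ pooled SDs apart at n = 20/20: essentially certain detection
  apart <- data.frame(group = rep(c("CF", "control"), each = 20),
                      EI = c(rnorm(20, 8, 1), rnorm(20, 4, 1)))
  expect_lt(compare_groups(apart, "EI")$p_value, 1e-3)
})

test_that("the rank-sum result is invariant under monotone transforms", {
  set.seed(71)
  df <- data.frame(group = rep(c("CF", "control"), each = 15),
                   EI = c(rexp(15, 0.2), rexp(15, 0.5)))
  p1 <- compare_groups(df, "EI", test = "wilcoxon")$p_value
  df$EI <- exp(df$EI / 10)  # strictly monotone
  p2 <- compare_groups(df, "EI", test = "wilcoxon")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("auto test selection follows the normality of both groups", {
  set.seed(72)
  norm_df <- data.frame(group = rep(c("CF", "control"), each = 30),
                        x = rnorm(60))
  expect_equal(compare_groups(norm_df, "x")$test, "t")
  skew_df <- data.frame(group = rep(c("CF", "control"), each = 30),
                        x = c(rexp(30)^3, rnorm(30, 10)))
  res <- compare_groups(skew_df, "x")
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$summary_style, "median_range")
})

test_that("perfect anticorrelation yields -1 for both methods", {
  x <- c(1, 3, 4, 7, 9, 12, 15)
  df <- data.frame(EI = x, FEV1pct = -x, group = "CF")
  out <- correlation_matrix(df, mdct_metrics = "EI", pft_metrics = "FEV1pct")
  expect_equal(out$coefficient, -1)
  expect_equal(out$method, "spearman")
  out2 <- correlation_matrix(df, mdct_metrics = "EI", pft_metrics = "FEV1pct")
  df$LV <- x; df$TLC <- -x
  out3 <- correlation_matrix(df, mdct_metrics = "LV", pft_metrics = "TLC")
  expect_equal(out3$method, "pearson")
  expect_equal(out3$coefficient, -1)
})

test_that("the Bonferroni flag is reproducible from p, alpha and m", {
  tab <- generate_cohort(cohort_spec(seed = 73))$table
  out <- correlation_matrix(tab, group = "CF")
  expect_equal(nrow(out), 6 * 7)
  expect_equal(unique(out$m_tests), 7L)
  recomputed <- !is.na(out$p_value) & out$p_value < 0.05 / out$m_tests
  expect_identical(out$significant_bonferroni, recomputed)
  # per-test threshold with m = 7 is 0.05 / 7 = 0.00714...
  expect_equal(0.05 / 7, 0.00714285714, tolerance = 1e-9)
})

test_that("method assignment follows the EI / percent-predicted rule", {
  tab <- generate_cohort(cohort_spec(seed = 74))$table
  out <- correlation_matrix(tab, group = "CF")
  sp <- out$method == "spearman"
  expect_true(all(sp[out$x_name == "EI"]))
  expect_true(all(sp[out$y_name %in% c("FEV1pct")]))
  expect_true(all(out$method[out$x_name == "LV" & out$y_name == "TLC"] == "pearson"))
})

test_that("Spearman is invariant to monotone transforms, Pearson to affine", {
  set.seed(75)
  x <- rnorm(25); y <- 0.6 * x + rnorm(25, 0, 0.5)
  df <- data.frame(EI = x, FEV1pct = y)
  r1 <- correlation_matrix(df, "EI", "FEV1pct")$coefficient
  df2 <- data.frame(EI = exp(x), FEV1pct = y^3 + 5 * y)
  r2 <- correlation_matrix(df2, "EI", "FEV1pct")$coefficient
  expect_equal(r1, r2, tolerance = 1e-12)
  df3 <- data.frame(LV = 2 * x + 3, TLC = -0.5 * y + 1)
  rp1 <- correlation_matrix(data.frame(LV = x, TLC = y), "LV", "TLC")$coefficient
  rp2 <- correlation_matrix(df3, "LV", "TLC")$coefficient
  expect_equal(rp1, -rp2, tolerance = 1e-12)
})

test_that("constant columns report an undefined correlation instead of failing", {
  df <- data.frame(EI = rep(0.1, 8), FEV1pct = 1:8)
  out <- correlation_matrix(df, "EI", "FEV1pct")
  expect_true(is.na(out$coefficient))
  expect_match(out$note, "constant")
})

test_that("small-sample Spearman p-values agree with the exact null", {
  # independent oracle: cor.test's exact Spearman distribution (no ties)
  cases <- list(list(x = 1:7, y = c(2, 1, 4, 3, 6, 5, 7)),
                list(x = 1:8, y = c(3, 1, 4, 2, 6, 8, 5, 7)),
                list(x = 1:7, y = c(6, 7, 4, 5, 1, 3, 2)))
  for (cs in cases) {
    df <- data.frame(EI = cs$x, FEV1pct = cs$y)
    ours <- correlation_matrix(df, "EI", "FEV1pct")
    ref <- cor.test(cs$x, cs$y, method = "spearman", exact = TRUE)
    expect_equal(ours$coefficient, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("variance explained truncates to the printed integer percent", {
  expect_identical(variance_explained(-0.66), 43)
  expect_identical(variance_explained(0), 0)
  expect_identical(variance_explained(1), 100)
  expect_identical(variance_explained(0.5), 25)
  expect_error(variance_explained(1.2), "\\[-1, 1\\]")
})

test_that("noiseless data recover the regression slope exactly", {
  age <- c(8, 12, 15, 21, 30, 44, 60)
  fit <- fit_age_regression(age, 0.35 * age + 1.0)
  expect_equal(fit$slope, 0.35, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)
})

test_that("the CI band has the closed-form width and is narrowest at the mean age", {
  set.seed(77)
  age <- runif(30, 5, 65)
  y <- 0.3 * age + rnorm(30, 0, 2)
  fit <- fit_age_regression(age, y)
  at_mean <- fit$band(fit$age_mean)
  expect_equal(at_mean$upper - at_mean$lower,
               2 * fit$t_crit * fit$residual_sd / sqrt(fit$n), tolerance = 1e-12)
  grid <- fit$band(seq(5, 65, by = 0.5))
  widths <- grid$upper - grid$lower
  expect_equal(grid$age[which.min(widths)], fit$age_mean, tolerance = 0.5)
  expect_true(all(grid$lower <= grid$fit & grid$fit <= grid$upper))
})

test_that("the band recomputes pointwise from the stored moments", {
  set.seed(78)
  age <- runif(25, 5, 60); y <- 0.2 * age + rnorm(25)
  fit <- fit_age_regression(age, y)
  a <- seq(6, 59, by = 3.7)
  manual_half <- fit$t_crit * fit$residual_sd *
    sqrt(1 / fit$n + (a - fit$age_mean)^2 / fit$age_sxx)
  b <- fit$band(a)
  expect_equal(b$upper - b$fit, manual_half, tolerance = 1e-12)
  expect_equal(b$fit, fit$intercept + fit$slope * a, tolerance = 1e-12)
})

test_that("identical cohorts never separate; designed cohorts separate near 13", {
  sim <- generate_cohort(cohort_spec(seed = 79))
  cf <- sim$table[sim$table$group == "CF", ]
  fit_cf <- fit_age_regression(cf$age, 100 * cf$EI)
  none <- ci_band_intersection(fit_cf, fit_cf, c(5, 65))
  expect_true(is.na(none$age))

  co <- sim$table[sim$table$group == "control", ]
  fit_co <- fit_age_regression(co$age, 100 * co$EI)
  hit <- ci_band_intersection(fit_cf, fit_co, c(5, 65))
  expect_false(is.na(hit$age))
  expect_lt(abs(hit$age - sim$truth$onset_age_design), 5)
})

test_that("slope comparison is symmetric and null-calibrated", {
  set.seed(80)
  age <- runif(30, 5, 60)
  y <- 0.2 * age + rnorm(30, 0, 1.5)
  same <- compare_slopes(age, y, age, y)
  expect_gt(same$p_value, 0.99)
  expect_equal(abs(same$slope_difference), 0, tolerance = 1e-12)

  sim <- generate_cohort(cohort_spec(seed = 81))
  cf <- sim$table[sim$table$group == "CF", ]
  co <- sim$table[sim$table$group == "control", ]
  ab <- compare_slopes(cf$age, 100 * cf$EI, co$age, 100 * co$EI)
  ba <- compare_slopes(co$age, 100 * co$EI, cf$age, 100 * cf$EI)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-9)
  expect_equal(ab$slope_difference, -ba$slope_difference, tolerance = 1e-9)
})

test_that("CT lung volume validates against TLC regardless of units", {
  sim <- generate_cohort(cohort_spec(seed = 82))
  out <- validate_lv_tlc(sim$table)
  expect_gt(out$coefficient, 0.9)
  tab2 <- sim$table
  tab2$LV <- tab2$LV / 1000  # litres instead of ml: r is scale-invariant
  expect_equal(validate_lv_tlc(tab2)$coefficient, out$coefficient,
               tolerance = 1e-12)
  exact <- data.frame(LV = sim$table$TLC * 1000, TLC = sim$table$TLC)
  expect_equal(validate_lv_tlc(exact)$coefficient, 1, tolerance = 1e-12)
})
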