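#' Compare a metric between two cohort groups
#'
#' Student's t-test when both groups pass a Shapiro-Wilk normality check at
#' 0.05, otherwise the Wilcoxon rank-sum test (`test = "auto"`). Group
#' summaries report mean +/- SD for the t-test and median with data range
#' otherwise, matching the usual descriptive convention.
#'
#' @param cohort Data frame with a `group` column and the metric column.
#' @param metric Column name to compare.
#' @param test `"auto"`, `"t"` or `"wilcoxon"`.
#' @param group_col Name of the grouping column (two levels).
#' @return A `group_comparison` list with `test`, `statistic`, `p_value`
#'   and per-group `summaries`.
#' @export
compare_groups <- function(cohort, metric, test = c("auto", "t", "wilcoxon"),
                           group_col = "group") {
  test <- match.arg(test)
  stopifnot(metric %in% names(cohort), group_col %in% names(cohort))
  g <- as.factor(cohort[[group_col]])
  levs <- levels(droplevels(g))
  if (length(levs) != 2L)
    stop("`group_col` must have exactly two levels", call. = FALSE)
  x <- cohort[[metric]][g == levs[1]]
  y <- cohort[[metric]][g == levs[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop(sprintf("metric '%s' is absent for all of one group", metric), call. = FALSE)
  if (test == "auto") {
    normal <- function(v) {
      if (length(v) < 3L || length(unique(v)) == 1L) return(FALSE)
      shapiro.test(v)$p.value > 0.05
    }
    test <- if (normal(x) && normal(y)) "t" else "wilcoxon"
  }
  res <- if (test == "t") t.test(x, y, var.equal = TRUE)
  else suppressWarnings(wilcox.test(x, y, exact = FALSE))
  summarise <- function(v) {
    list(n = length(v), mean = mean(v), sd = sd(v),
         median = median(v), range = range(v))
  }
  structure(
    list(metric = metric, test = test,
         statistic = unname(res$statistic), p_value = res$p.value,
         groups = levs,
         summaries = setNames(list(summarise(x), summarise(y)), levs),
         summary_style = if (test == "t") "mean_sd" else "median_range"),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s) {
    if (x$summary_style == "mean_sd")
      sprintf("%.3g +/- %.3g (n=%d)", s$mean, s$sd, s$n)
    else sprintf("%.3g (%.3g-%.3g) (n=%d)", s$median, s$range[1], s$range[2], s$n)
  }
  cat(sprintf("<group_comparison> %s: %s %s vs %s %s; %s test p = %.3g\n",
              x$metric, x$groups[1], fmt(x$summaries[[1]]),
              x$groups[2], fmt(x$summaries[[2]]), x$test, x$p_value))
  invisible(x)
}

# Rank-based metrics and percent-predicted values violate the linearity
# assumption behind Pearson's r, so those pairs use Spearman's rank
# correlation; absolute-valued physiology uses Pearson.
uses_spearman <- function(name) {
  name == "EI" || grepl("pct$", name)
}

# Spearman p-value: t approximation for n >= 10, exact permutation
# enumeration below (feasible since n <= 9 there).
spearman_p <- function(r, xr, yr) {
  n <- length(xr)
  if (is.na(r)) return(NA_real_)
  if (n >= 10L) {
    if (abs(r) >= 1) return(0)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    return(2 * pt(-abs(tstat), df = n - 2))
  }
  perms <- all_permutations(n)
  ry <- matrix(yr[perms], nrow = nrow(perms))
  rs <- as.vector((ry %*% xr) - n * mean(xr) * mean(yr)) /
    ((n - 1) * sd(xr) * sd(yr))
  mean(abs(rs) >= abs(r) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

cor_with_p <- function(x, y, method) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L)
    return(list(coefficient = NA_real_, p_value = NA_real_, n = n,
                note = "fewer than 4 paired observations"))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(coefficient = NA_real_, p_value = NA_real_, n = n,
                note = "undefined correlation: constant column"))
  if (method == "pearson") {
    ct <- cor.test(x, y, method = "pearson")
    list(coefficient = unname(ct$estimate), p_value = ct$p.value, n = n, note = NA_character_)
  } else {
    xr <- rank(x); yr <- rank(y)  # average ranks for ties
    r <- cor(xr, yr)
    list(coefficient = r, p_value = spearman_p(r, xr, yr), n = n, note = NA_character_)
  }
}

#' Correlation matrix of densitometry versus lung function
#'
#' One correlation per (densitometry metric, PFT metric) pair. Spearman's
#' rank correlation is used whenever either variable is EI or a
#' percent-predicted value, Pearson's r otherwise. Each p-value is flagged
#' against the Bonferroni-corrected threshold `alpha / m` where `m` is the
#' number of PFT metrics tested per densitometry parameter (7 with the
#' default variable lists).
#'
#' @param cohort Data frame of subject records.
#' @param mdct_metrics Densitometry columns (default LV, LW, EV, EI, MLD,
#'   perc15).
#' @param pft_metrics Lung-function columns (default FEV1, FEV1pct, VC,
#'   FEV1_VC, RV, TLC, RV_TLC).
#' @param alpha Family-wise significance level, default 0.05.
#' @param group Optional group level to subset on before correlating.
#' @return A data frame with one row per pair: `x_name`, `y_name`,
#'   `method`, `coefficient`, `p_value`, `n`, `m_tests`,
#'   `significant_bonferroni`, `note`.
#' @export
correlation_matrix <- function(cohort,
                               mdct_metrics = c("LV", "LW", "EV", "EI", "MLD", "perc15"),
                               pft_metrics = c("FEV1", "FEV1pct", "VC", "FEV1_VC",
                                               "RV", "TLC", "RV_TLC"),
                               alpha = 0.05, group = NULL) {
  if (!is.null(group)) cohort <- cohort[cohort$group == group, , drop = FALSE]
  missing_cols <- setdiff(c(mdct_metrics, pft_metrics), names(cohort))
  if (length(missing_cols))
    stop(sprintf("columns not in cohort: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  m <- length(pft_metrics)
  rows <- list()
  for (mx in mdct_metrics) {
    for (py in pft_metrics) {
      method <- if (uses_spearman(mx) || uses_spearman(py)) "spearman" else "pearson"
      res <- cor_with_p(cohort[[mx]], cohort[[py]], method)
      rows[[length(rows) + 1L]] <- data.frame(
        x_name = mx, y_name = py, method = method,
        coefficient = res$coefficient, p_value = res$p_value, n = res$n,
        m_tests = m,
        significant_bonferroni = !is.na(res$p_value) && res$p_value < alpha / m,
        note = res$note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Variance explained by a correlation
#'
#' `100 * r^2`, truncated (not rounded) to an integer percent for display:
#' r = -0.66 gives 43 (0.66^2 = 43.56).
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @return Integer percent.
#' @export
variance_explained <- function(r) {
  if (!is.numeric(r) || any(abs(r) > 1))
    stop("`r` must be a correlation coefficient in [-1, 1]", call. = FALSE)
  trunc(100 * r^2)
}

#' Ordinary least squares of a metric on age, with mean-response CI band
#'
#' Fits `y ~ age` and carries the closed-form t-based confidence band for
#' the mean response: `fit(a) +/- t * s * sqrt(1/n + (a - mean(age))^2 / Sxx)`.
#' The band is narrowest at the mean age by construction.
#'
#' @param age Ages in years.
#' @param y Response values (for emphysema-index regressions use percent
#'   units, so slopes are in %/year).
#' @param ci_level Confidence level, default 0.95.
#' @return A `regression_band` with `slope`, `intercept`, `residual_sd`,
#'   `n`, `ci_level`, age moments, and `band(age)` returning a data frame
#'   of `fit`, `lower`, `upper`.
#' @export
fit_age_regression <- function(age, y, ci_level = 0.95) {
  keep <- complete.cases(age, y)
  age <- age[keep]; y <- y[keep]
  n <- length(age)
  if (n < 3L || length(unique(age)) < 3L)
    stop("degenerate design: need at least 3 distinct ages", call. = FALSE)
  fit <- lm(y ~ age)
  s <- sqrt(sum(fit$residuals^2) / (n - 2))
  xbar <- mean(age)
  sxx <- sum((age - xbar)^2)
  tcrit <- qt(1 - (1 - ci_level) / 2, df = n - 2)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  band <- function(a) {
    f <- intercept + slope * a
    half <- tcrit * s * sqrt(1 / n + (a - xbar)^2 / sxx)
    data.frame(age = a, fit = f, lower = f - half, upper = f + half)
  }
  structure(
    list(slope = slope, intercept = intercept, residual_sd = s, n = n,
         ci_level = ci_level, age_mean = xbar, age_sxx = sxx,
         t_crit = tcrit, band = band),
    class = "regression_band")
}

#' @export
print.regression_band <- function(x, ...) {
  cat(sprintf("<regression_band> y = %.4g + %.4g * age (n = %d, residual SD %.3g, %g%% CI)\n",
              x$intercept, x$slope, x$n, x$residual_sd, 100 * x$ci_level))
  invisible(x)
}

#' First age at which two regression CI bands separate
#'
#' Operationalises the "intersection of the 95% confidence limits" between
#' a diseased and a control age-regression: the smallest age at which the
#' lower band of the first fit reaches or exceeds the upper band of the
#' second, located by coarse scan plus bisection to 0.1-year precision.
#'
#' @param band_a,band_b [fit_age_regression()] results; separation means
#'   `band_a$lower >= band_b$upper`.
#' @param age_range Length-2 numeric, the age interval searched.
#' @param precision Bisection precision in years.
#' @return A list with `age` (NA if the bands never separate in range) and
#'   `separated_at_start` (TRUE if already separate at the range minimum).
#' @export
ci_band_intersection <- function(band_a, band_b, age_range, precision = 0.1) {
  stopifnot(inherits(band_a, "regression_band"), inherits(band_b, "regression_band"),
            length(age_range) == 2L, age_range[1] < age_range[2])
  gap <- function(a) band_a$band(a)$lower - band_b$band(a)$upper
  if (gap(age_range[1]) >= 0)
    return(list(age = age_range[1], separated_at_start = TRUE))
  grid <- seq(age_range[1], age_range[2], by = min(0.25, precision))
  gv <- vapply(grid, gap, numeric(1))
  first <- which(gv >= 0)
  if (length(first) == 0L)
    return(list(age = NA_real_, separated_at_start = FALSE))
  lo <- grid[first[1] - 1L]; hi <- grid[first[1]]
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (gap(mid) >= 0) hi <- mid else lo <- mid
  }
  list(age = hi, separated_at_start = FALSE)
}

#' Test equality of two age-regression slopes
#'
#' Pooled linear model with a group-by-age interaction (ANCOVA); the
#' two-sided p-value of the interaction coefficient tests slope equality
#' using the pooled residual variance.
#'
#' @param age1,y1 Data for the first group.
#' @param age2,y2 Data for the second group.
#' @return A list with `p_value`, `slope_difference` and `statistic`.
#' @export
compare_slopes <- function(age1, y1, age2, y2) {
  k1 <- complete.cases(age1, y1); k2 <- complete.cases(age2, y2)
  age1 <- age1[k1]; y1 <- y1[k1]; age2 <- age2[k2]; y2 <- y2[k2]
  if (length(age1) < 3L || length(age2) < 3L)
    stop("degenerate design: need at least 3 points per group", call. = FALSE)
  df <- data.frame(age = c(age1, age2), y = c(y1, y2),
                   grp = factor(rep(c("a", "b"), c(length(age1), length(age2)))))
  fit <- lm(y ~ age * grp, data = df)
  sm <- summary(fit)$coefficients
  row <- grep("^age:grp", rownames(sm))
  list(p_value = unname(sm[row, 4]),
       slope_difference = unname(sm[row, 1]),
       statistic = unname(sm[row, 3]))
}

#' Validate CT lung volume against plethysmographic TLC
#'
#' Pooled (both groups) Pearson correlation of the CT-derived lung volume
#' (converted to litres) with total lung capacity; CT inspiratory lung
#' volume tracks TLC up to an anatomical dead-space offset.
#'
#' @param cohort Data frame with `LV` (ml) and `TLC` (l) columns.
#' @return A one-row data frame in [correlation_matrix()] format.
#' @export
validate_lv_tlc <- function(cohort) {
  stopifnot(all(c("LV", "TLC") %in% names(cohort)))
  res <- cor_with_p(cohort$LV / 1000, cohort$TLC, "pearson")
  data.frame(x_name = "LV", y_name = "TLC", method = "pearson",
             coefficient = res$coefficient, p_value = res$p_value, n = res$n,
             m_tests = 1L,
             significant_bonferroni = !is.na(res$p_value) && res$p_value < 0.05,
             note = res$note, stringsAsFactors = FALSE)
}

#' Dot plot of a metric against age with regression CI bands
#'
#' Reproduces the style of cohort age-progression figures: per-group dot
#' plots, fitted regression lines and dashed 95% confidence bands for the
#' mean response. Requires ggplot2.
#'
#' @param cohort Data frame with `age`, `group` and the metric column.
#' @param metric Column to plot (for EI, values are shown in percent).
#' @param ci_level Confidence level for the bands.
#' @return A ggplot object.
#' @export
plot_age_regression <- function(cohort, metric = "EI", ci_level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_age_regression requires the ggplot2 package", call. = FALSE)
  y <- cohort[[metric]]
  ylab <- metric
  if (metric == "EI") { y <- 100 * y; ylab <- "EI [%]" }
  df <- data.frame(age = cohort$age, y = y, group = cohort$group)
  bands <- do.call(rbind, lapply(split(df, df$group), function(sub) {
    fit <- fit_age_regression(sub$age, sub$y, ci_level)
    cbind(group = sub$group[1], fit$band(seq(min(sub$age), max(sub$age),
                                             length.out = 80)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(y = .data$fit, group = .data$group)) +
    ggplot2::geom_line(data = bands, linetype = "dashed",
                       ggplot2::aes(y = .data$lower, group = .data$group)) +
    ggplot2::geom_line(data = bands, linetype = "dashed",
                       ggplot2::aes(y = .data$upper, group = .data$group)) +
    ggplot2::labs(x = "age [years]", y = ylab, colour = NULL) +
    ggplot2::theme_classic()
}
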