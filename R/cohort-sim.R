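#' Cohort specification
#'
#' Parameterises the synthetic CF-versus-control cohort: group sizes and
#' age structure, the emphysema-index-versus-age lines per group, the
#' rank-correlation target linking EI to FEV1 percent predicted, and the
#' CT-volume-versus-TLC link. Defaults reproduce the published study
#' conditions: 41 CF subjects (median age ~20 years, range 7-66) versus 21
#' controls (median ~30, range 4-68), EI slopes 0.35 versus 0.04 %/year,
#' Spearman(EI, FEV1%) target -0.66 in CF, and EI intercepts placed so the
#' expected 95% confidence bands of the two age regressions first separate
#' at ~13 years of age.
#'
#' Residual EI noise is measurement-scale (about 1 %EI): the generator
#' reproduces the mean age structure and the correlation sign structure of
#' the study, not its full population heterogeneity (see the methods
#' vignette).
#'
#' @param n_cf,n_control Group sizes. Defaults 41 and 21.
#' @param age_range_cf,age_range_control Age ranges in years.
#' @param ei_slope_cf,ei_slope_control EI-on-age slopes in %EI per year.
#' @param ei_intercept_cf,ei_intercept_control Intercepts in %EI.
#' @param ei_noise_sd_cf,ei_noise_sd_control Residual SD around the EI
#'   lines, in %EI. EI is floored at 0 after noise.
#' @param target_spearman_ei_fev1 Spearman target for EI vs FEV1% in CF,
#'   achieved through a Gaussian-copula normal-score blend with
#'   `rho = 2 sin(pi * rho_s / 6)`.
#' @param lv_tlc_offset_ml,lv_noise_sd_ml CT lung volume is
#'   `TLC * 1000 - offset + noise` (anatomical dead space and
#'   breath-hold depth difference).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cf = 41, n_control = 21,
                        age_range_cf = c(7, 66), age_range_control = c(4, 68),
                        ei_slope_cf = 0.35, ei_slope_control = 0.04,
                        ei_intercept_cf = -2.21, ei_intercept_control = 0.5,
                        ei_noise_sd_cf = 1.2, ei_noise_sd_control = 1.1,
                        target_spearman_ei_fev1 = -0.66,
                        lv_tlc_offset_ml = 400, lv_noise_sd_ml = 250,
                        seed = 1L) {
  if (n_cf < 1 || n_control < 1) stop("group sizes must be positive", call. = FALSE)
  if (abs(target_spearman_ei_fev1) >= 1)
    stop("|target_spearman_ei_fev1| must be < 1", call. = FALSE)
  if (ei_noise_sd_cf < 0 || ei_noise_sd_control < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(
    list(n_cf = as.integer(n_cf), n_control = as.integer(n_control),
         age_range_cf = age_range_cf, age_range_control = age_range_control,
         ei_slope_cf = ei_slope_cf, ei_slope_control = ei_slope_control,
         ei_intercept_cf = ei_intercept_cf,
         ei_intercept_control = ei_intercept_control,
         ei_noise_sd_cf = ei_noise_sd_cf,
         ei_noise_sd_control = ei_noise_sd_control,
         target_spearman_ei_fev1 = target_spearman_ei_fev1,
         lv_tlc_offset_ml = lv_tlc_offset_ml, lv_noise_sd_ml = lv_noise_sd_ml,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# Age draws. CF ages: right-skewed shifted gamma (children and young
# adults dominate a CF clinic population), truncated to the range by
# redraw. Control ages: scaled beta, roughly symmetric.
draw_ages_cf <- function(n, rng) {
  span <- rng[2] - rng[1]
  g <- rgamma(n, shape = 1.7, scale = 9.4)
  while (any(g > span)) g[g > span] <- rgamma(sum(g > span), shape = 1.7, scale = 9.4)
  rng[1] + g
}

draw_ages_control <- function(n, rng) {
  rng[1] + (rng[2] - rng[1]) * rbeta(n, 1.55, 1.95)
}

# Expected age moments under the two sampling schemes, used by the design
# onset solver. Deterministic (large fixed-seed Monte Carlo), cached per
# age-range combination.
.moments_cache <- new.env(parent = emptyenv())

expected_age_moments <- function(spec) {
  key <- paste(c(spec$age_range_cf, spec$age_range_control), collapse = "|")
  hit <- .moments_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- with_seed(20130821, {
    a_cf <- draw_ages_cf(2e5, spec$age_range_cf)
    a_co <- draw_ages_control(2e5, spec$age_range_control)
    list(cf = list(mean = mean(a_cf), var = var_pop(a_cf)),
         control = list(mean = mean(a_co), var = var_pop(a_co)))
  })
  .moments_cache[[key]] <- out
  out
}

var_pop <- function(x) mean((x - mean(x))^2)

#' Designed onset age of band separation
#'
#' Solves, on the generator's design (true lines, expected age moments,
#' nominal residual SDs), for the smallest age at which the lower 95%
#' confidence band of the CF age-regression reaches the upper band of the
#' control regression. This is the "designed crossing" that realized
#' cohorts scatter around; at the default specification it sits near 13
#' years.
#'
#' @param spec A [cohort_spec()].
#' @param ci_level Confidence level of the bands.
#' @return Age in years (NA if the design bands never separate in range).
#' @export
design_onset_age <- function(spec = cohort_spec(), ci_level = 0.95) {
  mom <- expected_age_moments(spec)
  half <- function(n, s, mean_a, var_a) {
    tcrit <- qt(1 - (1 - ci_level) / 2, df = n - 2)
    function(a) tcrit * s * sqrt(1 / n + (a - mean_a)^2 / (n * var_a))
  }
  h_cf <- half(spec$n_cf, spec$ei_noise_sd_cf, mom$cf$mean, mom$cf$var)
  h_co <- half(spec$n_control, spec$ei_noise_sd_control,
               mom$control$mean, mom$control$var)
  gap <- function(a) {
    (spec$ei_intercept_cf + spec$ei_slope_cf * a - h_cf(a)) -
      (spec$ei_intercept_control + spec$ei_slope_control * a + h_co(a))
  }
  lo <- max(spec$age_range_cf[1], spec$age_range_control[1])
  hi <- min(spec$age_range_cf[2], spec$age_range_control[2])
  if (gap(lo) >= 0) return(lo)
  if (gap(hi) < 0) return(NA_real_)
  uniroot(gap, c(lo, hi), tol = 0.01)$root
}

# normal scores of ranks, the Gaussian-copula backbone
normal_scores <- function(x) qnorm((rank(x, ties.method = "average") - 0.5) / length(x))

# blend a latent normal with fresh noise at correlation rho
blend <- function(z, rho) rho * z + sqrt(1 - rho^2) * rnorm(length(z))

# gamma quantile with given mean and sd, via probability p
qgamma_ms <- function(p, mean, sd) {
  shape <- (mean / sd)^2
  qgamma(p, shape = shape, scale = mean / shape)
}

#' Generate a synthetic CF-versus-control cohort
#'
#' Ages are drawn per group; EI (%) follows the group's line plus Gaussian
#' noise, floored at 0. FEV1% is linked to EI through a Gaussian copula
#' calibrated to the Spearman target; TLC, RV/TLC (hence RV and VC), lung
#' weight, MLD and the 15th percentile carry the sign structure of the
#' published correlation table (perc15 decreasing in EI, LW increasing in
#' RV, RV/TLC increasing in EI). CT lung volume is TLC minus an offset plus
#' noise. PFT values are set missing for 2 CF and 6 control subjects,
#' matching the published PFT subgroup sizes (39 and 15).
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_sim` list: `table` (data frame of subject records) and
#'   `truth` (generator parameters, including `onset_age_design` and the
#'   copula rho used for the FEV1% link).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rho_fev <- 2 * sin(pi * spec$target_spearman_ei_fev1 / 6)
  tab <- with_seed(spec$seed, {
    cf <- generate_group(spec, "CF", spec$n_cf, rho_fev)
    co <- generate_group(spec, "control", spec$n_control, rho_fev)
    tab <- rbind(cf, co)
    # PFT missingness: published PFT subgroups are 39 CF / 15 control
    pft_cols <- c("FEV1", "FEV1pct", "VC", "VCpct", "FEV1_VC",
                  "RV", "RVpct", "TLC", "TLCpct", "RV_TLC")
    drop_cf <- sample(which(tab$group == "CF"), min(2L, spec$n_cf - 1L))
    drop_co <- sample(which(tab$group == "control"), min(6L, spec$n_control - 1L))
    tab[c(drop_cf, drop_co), pft_cols] <- NA_real_
    tab
  })
  structure(
    list(table = tab,
         truth = list(spec = spec,
                      onset_age_design = design_onset_age(spec),
                      rho_fev1_copula = rho_fev)),
    class = "cohort_sim")
}

generate_group <- function(spec, group, n, rho_fev) {
  is_cf <- group == "CF"
  age <- if (is_cf) draw_ages_cf(n, spec$age_range_cf)
  else draw_ages_control(n, spec$age_range_control)
  slope <- if (is_cf) spec$ei_slope_cf else spec$ei_slope_control
  icpt <- if (is_cf) spec$ei_intercept_cf else spec$ei_intercept_control
  nsd <- if (is_cf) spec$ei_noise_sd_cf else spec$ei_noise_sd_control
  ei_pct <- pmin(100, pmax(0, slope * age + icpt + rnorm(n, 0, nsd)))

  z_ei <- normal_scores(ei_pct)
  # FEV1%: copula-linked (decreasing) in CF, healthy and EI-independent in
  # controls; gamma marginals keep values positive and right-skewed
  fev1pct <- if (is_cf) qgamma_ms(pnorm(blend(z_ei, rho_fev)), 46, 30)
  else qgamma_ms(pnorm(rnorm(n)), 102, 16)
  # TLC rises with EI in CF (hyperinflation); normal-range in controls
  tlc <- if (is_cf) qgamma_ms(pnorm(blend(z_ei, 0.55)), 5.3, 2.1)
  else qgamma_ms(pnorm(rnorm(n)), 5.9, 0.8)
  # RV/TLC: bounded hyperinflation index, increasing in EI in CF
  rv_tlc <- if (is_cf) 0.2 + 0.65 * qbeta(pnorm(blend(z_ei, 0.49)), 3, 3)
  else 0.15 + 0.55 * qbeta(pnorm(rnorm(n)), 4, 9)
  rv <- rv_tlc * tlc
  vc <- tlc - rv
  # percent-predicted scaffolding: crude paediatric-to-adult growth factor
  growth <- pmin(1, age / 19)^1.4
  pred_fev <- 3.65 * growth
  fev1 <- pmin(fev1pct / 100 * pred_fev, 0.92 * vc)
  fev1_vc <- fev1 / vc
  vcpct <- vc / (4.15 * growth) * 100
  rvpct <- rv / (1.75 * pmin(1, age / 19)^1.2) * 100
  tlcpct <- tlc / (5.8 * pmin(1, age / 19)^1.3) * 100
  # densitometry companions: perc15 falls and LW rises with disease
  perc15 <- -912 - 3.0 * ei_pct + rnorm(n, 0, 6)
  mld <- -851 - 0.5 * ei_pct + rnorm(n, 0, 10)
  z_rv <- normal_scores(rv)
  lw <- if (is_cf) qgamma_ms(pnorm(blend(z_rv, 0.8)), 950, 220)
  else qgamma_ms(pnorm(blend(z_rv, 0.8)), 760, 140)
  lv <- pmax(300, tlc * 1000 - spec$lv_tlc_offset_ml + rnorm(n, 0, spec$lv_noise_sd_ml))
  ei <- ei_pct / 100
  sex <- if (is_cf) sample(rep(c("M", "F"), c(22, 19))[seq_len(min(n, 41))],
                           n, replace = n > 41)
  else sample(rep(c("M", "F"), c(13, 8))[seq_len(min(n, 21))], n, replace = n > 21)
  data.frame(
    id = sprintf("%s%02d", if (is_cf) "CF" else "CO", seq_len(n)),
    group = group, age = age, sex = sex,
    FEV1 = fev1, FEV1pct = fev1pct, VC = vc, VCpct = vcpct, FEV1_VC = fev1_vc,
    RV = rv, RVpct = rvpct, TLC = tlc, TLCpct = tlcpct, RV_TLC = rv_tlc,
    LV = lv, EV = ei * lv, EI = ei, MLD = mld, LW = lw, perc15 = perc15,
    pft_mdct_gap_days = draw_gap_days(n),
    stringsAsFactors = FALSE)
}

# short PFT-to-CT gaps: most same-day, occasional long tails (<= 73 days)
draw_gap_days <- function(n) {
  g <- stats::rgeom(n, prob = 0.35)
  pmin(g, 73L)
}

#' Write a cohort table to CSV
#'
#' One row per subject, columns named as the subject-record fields, missing
#' values as empty cells.
#'
#' @param cohort A `cohort_sim` or the table itself.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- if (inherits(cohort, "cohort_sim")) cohort$table else cohort
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with subject-record columns.
#' @return A data frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d CF / %d control subjects; designed onset age %.1f y\n",
              sum(x$table$group == "CF"), sum(x$table$group == "control"),
              x$truth$onset_age_design))
  invisible(x)
}
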