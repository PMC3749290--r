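#' Pipeline configuration
#'
#' One configuration object ties the stages together: synthetic inputs,
#' segmentation parameters, densitometry threshold, statistics settings
#' and output location. Every default equals the corresponding
#' module-level default, and a config round-trips through YAML.
#'
#' @param output_dir Directory for all outputs.
#' @param seed Master seed; all stage randomness derives from it.
#' @param emphysema_threshold_hu Density-mask threshold. Default -950.
#' @param calibration_tolerance_hu Air-calibration tolerance. Default 6.
#' @param alpha,m_tests Statistics: family-wise alpha and Bonferroni test
#'   count per densitometry parameter.
#' @param phantom A [phantom_spec()] (or list of its fields).
#' @param cohort A [cohort_spec()] (or list of its fields).
#' @param segmentation A [segment_params()] (or list of its fields).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir = "lungdens-out", seed = 1L,
                            emphysema_threshold_hu = -950,
                            calibration_tolerance_hu = 6,
                            alpha = 0.05, m_tests = 7L,
                            phantom = phantom_spec(seed = seed),
                            cohort = cohort_spec(seed = seed),
                            segmentation = segment_params()) {
  if (is.list(phantom) && !inherits(phantom, "phantom_spec"))
    phantom <- do.call(phantom_spec, phantom)
  if (is.list(cohort) && !inherits(cohort, "cohort_spec"))
    cohort <- do.call(cohort_spec, cohort)
  if (is.list(segmentation) && !inherits(segmentation, "segmentation_params"))
    segmentation <- do.call(segment_params, segmentation)
  structure(
    list(output_dir = output_dir, seed = as.integer(seed),
         emphysema_threshold_hu = emphysema_threshold_hu,
         calibration_tolerance_hu = calibration_tolerance_hu,
         alpha = alpha, m_tests = as.integer(m_tests),
         phantom = phantom, cohort = cohort, segmentation = segmentation),
    class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` the config.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), identity, how = "replace")
  plain$phantom <- unclass(config$phantom)
  plain$cohort <- unclass(config$cohort)
  plain$segmentation <- unclass(config$segmentation)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    output_dir = raw$output_dir, seed = raw$seed,
    emphysema_threshold_hu = raw$emphysema_threshold_hu,
    calibration_tolerance_hu = raw$calibration_tolerance_hu,
    alpha = raw$alpha, m_tests = raw$m_tests,
    phantom = raw$phantom, cohort = raw$cohort,
    segmentation = raw$segmentation)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes phantom generation, segmentation, densitometry, cohort
#' generation and cohort statistics, writing versioned JSON/CSV outputs
#' and a manifest (package version, seed, parameters, per-file MD5
#' checksums) that suffices to re-run any stage reproducibly. A failed
#' stage propagates as an error after the manifest records the stages
#' completed so far.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-stage results and the manifest path.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  stages <- character(0)
  emit <- function(x, file) {
    path <- file.path(config$output_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  say("stage 1/4: phantom generation")
  ph <- generate_phantom(config$phantom)
  vol_path <- file.path(config$output_dir, "phantom.nii.gz")
  write_volume(ph$volume, vol_path)
  outputs <- c(outputs, vol_path)
  stages <- c(stages, "simulate_phantom")

  say("stage 2/4: lung segmentation")
  seg <- segment_lungs(ph$volume, config$segmentation,
                       calibration_tolerance = config$calibration_tolerance_hu)
  lung_path <- file.path(config$output_dir, "lung_mask.nii.gz")
  write_volume(seg$lung_mask, lung_path)
  outputs <- c(outputs, lung_path)
  stages <- c(stages, "segment")

  say("stage 3/4: densitometry")
  emph <- compute_density_mask(ph$volume, seg$lung_mask,
                               config$emphysema_threshold_hu)
  reports <- lapply(c("whole", "right", "left"), function(sc)
    compute_report(ph$volume, seg$lung_mask, emph, scope = sc,
                   threshold = config$emphysema_threshold_hu))
  names(reports) <- c("whole", "right", "left")
  emit(list(schema_version = "1.0",
            threshold_hu = config$emphysema_threshold_hu,
            designed_emphysema_fraction = ph$achieved_fraction,
            reports = lapply(reports, function(r)
              r[c("scope", "LV", "EV", "EI", "MLD", "LW", "perc15")])),
       "densitometry.json")
  stages <- c(stages, "densito")

  say("stage 4/4: cohort statistics")
  sim <- generate_cohort(config$cohort)
  cohort_path <- file.path(config$output_dir, "cohort.csv")
  write_cohort_csv(sim, cohort_path)
  outputs <- c(outputs, cohort_path)
  cf <- sim$table[sim$table$group == "CF", ]
  co <- sim$table[sim$table$group == "control", ]
  cors <- rbind(cbind(group = "CF", correlation_matrix(sim$table, group = "CF",
                                                       alpha = config$alpha)),
                cbind(group = "control", correlation_matrix(sim$table, group = "control",
                                                            alpha = config$alpha)))
  cor_path <- file.path(config$output_dir, "correlations.csv")
  write.csv(cors, cor_path, row.names = FALSE)
  outputs <- c(outputs, cor_path)
  cmp <- lapply(c("EV", "EI", "LW", "MLD", "perc15", "LV"), function(mname)
    compare_groups(sim$table, mname))
  cmp_df <- do.call(rbind, lapply(cmp, function(x)
    data.frame(metric = x$metric, test = x$test, p_value = x$p_value,
               stringsAsFactors = FALSE)))
  cmp_path <- file.path(config$output_dir, "group_comparisons.csv")
  write.csv(cmp_df, cmp_path, row.names = FALSE)
  outputs <- c(outputs, cmp_path)
  fit_cf <- fit_age_regression(cf$age, 100 * cf$EI)
  fit_co <- fit_age_regression(co$age, 100 * co$EI)
  onset <- ci_band_intersection(fit_cf, fit_co,
                                range(sim$table$age))
  slopes <- compare_slopes(cf$age, 100 * cf$EI, co$age, 100 * co$EI)
  ei_fev <- cor_with_p(cf$EI, cf$FEV1pct, "spearman")
  emit(list(schema_version = "1.0",
            slope_cf = fit_cf$slope, slope_control = fit_co$slope,
            slope_difference_p = slopes$p_value,
            onset_age = onset$age,
            onset_age_design = sim$truth$onset_age_design,
            spearman_ei_fev1pct_cf = ei_fev$coefficient,
            variance_explained_pct = variance_explained(ei_fev$coefficient),
            lv_tlc_pearson = validate_lv_tlc(sim$table)$coefficient),
       "regression_report.json")
  stages <- c(stages, "cohort")

  manifest <- list(
    schema_version = "1.0",
    package = "lungdens",
    version = as.character(utils::packageVersion("lungdens")),
    seed = config$seed,
    stages = stages,
    parameters = list(
      emphysema_threshold_hu = config$emphysema_threshold_hu,
      calibration_tolerance_hu = config$calibration_tolerance_hu,
      alpha = config$alpha, m_tests = config$m_tests,
      phantom = unclass(config$phantom)[setdiff(names(config$phantom), "cysts")],
      cohort = unclass(config$cohort),
      segmentation = unclass(config$segmentation)),
    checksums = as.list(tools::md5sum(sort(outputs))))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: %d stages, manifest at %s", length(stages), manifest_path)
  invisible(list(phantom = ph, segmentation = seg, reports = reports,
                 cohort = sim, manifest = manifest_path))
}
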