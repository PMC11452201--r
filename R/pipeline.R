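#' Default run configuration
#'
#' Nested list of all pipeline parameters, mirroring the module structure:
#' `phantom`, `preprocess`, `segment`, `morphometry`, `stats`, plus a global
#' `seed`, an output directory and a log level. `read_run_config()` loads a
#' YAML file and merges it over these defaults, so a config file only needs
#' the entries it changes; the fully resolved configuration is written next
#' to the results of every run.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "fibromorph_run",
    log_level = "info",
    phantom = list(
      enabled = TRUE,
      shape = c(96L, 96L, 96L),
      voxel_size_um = 1.6,
      stages = list(label = c("4wk", "6wk", "8wk"),
                    lesion_target_fraction = c(0.05, 0.20, 0.40)),
      n_replicates = 5L,
      sinusoid_radius_healthy_um = 5,
      sinusoid_radius_lesion_um = 9,
      sinusoid_fraction_healthy = 0.12,
      sinusoid_fraction_lesion = 0.07,
      n_vessels = 1L,
      vessel_radius_um = 16,
      bias_gradient = c(5e-4, 5e-4, 5e-4),
      artifact_density = 1e-4,
      noise_sd = 0.05
    ),
    preprocess = list(factor = 1L, percentile = 99.5),
    segment = list(
      use_truth_masks = FALSE,
      polarity = "lumen_dark",
      lumen_threshold_method = "otsu",
      vessel_min_radius_um = 12,
      min_object_voxels = 27L,
      lesion_reach_um = NULL,
      min_caliber_ratio = 1.4,
      opening_radius_um = 5,
      closing_radius_um = 10,
      min_lesion_diameter_um = 25
    ),
    stats = list(alpha = 0.05, control_stage = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @rdname default_run_config
#' @param path path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(default_run_config(), yaml::read_yaml(path))
}

cohort_from_config <- function(config) {
  ph <- config$phantom
  schedule <- cohort_schedule(ph$stages$label,
                              ph$stages$lesion_target_fraction,
                              n_replicates = ph$n_replicates,
                              base_seed = config$seed)
  template <- phantom_spec(
    shape = ph$shape, voxel_size_um = ph$voxel_size_um,
    sinusoid_radius_healthy_um = ph$sinusoid_radius_healthy_um,
    sinusoid_radius_lesion_um = ph$sinusoid_radius_lesion_um,
    sinusoid_fraction_healthy = ph$sinusoid_fraction_healthy,
    sinusoid_fraction_lesion = ph$sinusoid_fraction_lesion,
    n_vessels = ph$n_vessels, vessel_radius_um = ph$vessel_radius_um,
    bias_gradient = ph$bias_gradient,
    artifact_density = ph$artifact_density, noise_sd = ph$noise_sd,
    seed = config$seed)
  list(schedule = schedule, template = template)
}

seg_config_from_config <- function(config) {
  sg <- config$segment
  segmenter_config(
    polarity = sg$polarity,
    lumen_threshold_method = sg$lumen_threshold_method,
    fixed_threshold = sg$fixed_threshold,
    vessel_min_radius_um = sg$vessel_min_radius_um,
    min_object_voxels = sg$min_object_voxels,
    lesion_reach_um = sg$lesion_reach_um,
    min_caliber_ratio = sg$min_caliber_ratio,
    opening_radius_um = sg$opening_radius_um,
    closing_radius_um = sg$closing_radius_um,
    min_lesion_diameter_um = sg$min_lesion_diameter_um)
}

log_msg <- function(config, level, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(...)))
}

#' Build the long-format sample table from a morphometry result table
#'
#' Reshapes the per-sample morphometry rows (one row per sample, as written
#' to `results.csv`) into the long [sample_table()] format used by the group
#' tests: lesion volume proportion as a whole-sample metric, sinusoid volume
#' proportion and mean sinusoid thickness split by region.
#'
#' @param results data frame with [quantify_sample()] columns plus `label`
#'   (stage) and optional `phenotype`.
#' @return A [sample_table()].
#' @export
morphometry_to_sample_table <- function(results) {
  phen <- if ("phenotype" %in% names(results)) results$phenotype else "NIF"
  long <- rbind(
    data.frame(sample_id = results$sample_id, phenotype = phen,
               age_group = results$label, region = NA_character_,
               metric = "lesion_volume_proportion",
               value = results$lesion_volume_proportion),
    data.frame(sample_id = results$sample_id, phenotype = phen,
               age_group = results$label, region = "lesion",
               metric = "sinusoid_volume_proportion",
               value = results$sinusoid_volume_proportion_lesion),
    data.frame(sample_id = results$sample_id, phenotype = phen,
               age_group = results$label, region = "healthy",
               metric = "sinusoid_volume_proportion",
               value = results$sinusoid_volume_proportion_healthy),
    data.frame(sample_id = results$sample_id, phenotype = phen,
               age_group = results$label, region = "lesion",
               metric = "sinusoid_thickness_mean",
               value = results$thickness_mean_lesion),
    data.frame(sample_id = results$sample_id, phenotype = phen,
               age_group = results$label, region = "healthy",
               metric = "sinusoid_thickness_mean",
               value = results$thickness_mean_healthy))
  sample_table(long)
}

#' Stage-comparison statistics for a quantified cohort
#'
#' Applies the statistical battery used for staged morphometry readouts:
#' Kruskal-Wallis with Dunn post hoc tests on the lesion volume proportion
#' across stages; two-way ANOVA (region by stage) with the
#' interaction-triggered one-way/Dunnett fallback for mean sinusoid
#' thickness and for the sinusoid volume proportion; and per-stage unpaired
#' t-tests (lesion vs unaffected thickness) with Bonferroni correction.
#'
#' @param tab a [sample_table()].
#' @param alpha interaction significance threshold for the ANOVA fallback.
#' @param control_stage control level for Dunnett comparisons; defaults to
#'   the first stage.
#' @return Named list of `test_report`s.
#' @export
cohort_stats <- function(tab, alpha = 0.05, control_stage = NULL) {
  stages <- unique(tab$age_group)
  if (is.null(control_stage)) control_stage <- stages[1]
  out <- list()
  try_test <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      new_test_report(name, NA_character_, character(), NA_real_, NA_real_,
                      NA_real_, NULL, "none",
                      trace = paste("not run:", conditionMessage(e)),
                      flags = "skipped")
    })
  }
  out$lesion_proportion_kruskal <- try_test(kruskal_dunn(
    tab, "lesion_volume_proportion", "age_group"), "kruskal_dunn")
  has_regions <- function(metric) {
    sub <- tab[tab$metric == metric & !is.na(tab$value), ]
    length(unique(sub$region[!is.na(sub$region)])) >= 2L
  }
  if (has_regions("sinusoid_thickness_mean"))
    out$thickness_anova <- try_test(anova_with_fallback(
      tab, "sinusoid_thickness_mean", factor_a = "age_group",
      factor_b = "region", alpha = alpha, control_level = control_stage),
      "anova_with_fallback")
  if (has_regions("sinusoid_volume_proportion"))
    out$sinusoid_proportion_anova <- try_test(anova_with_fallback(
      tab, "sinusoid_volume_proportion", factor_a = "age_group",
      factor_b = "region", alpha = alpha, control_level = control_stage),
      "anova_with_fallback")
  # lesion vs unaffected thickness within each stage, Bonferroni family
  th <- tab[tab$metric == "sinusoid_thickness_mean" & !is.na(tab$value), ]
  if (nrow(th)) {
    th$stage_region <- paste(th$age_group, th$region, sep = ":")
    th$metric <- "sinusoid_thickness_mean"
    fam <- lapply(stages, function(s) paste(s, c("lesion", "healthy"),
                                            sep = ":"))
    fam <- fam[vapply(fam, function(pr)
      all(pr %in% th$stage_region) &&
        all(table(th$stage_region)[pr] >= 2), TRUE)]
    if (length(fam))
      out$thickness_region_t <- pairwise_t_bonferroni(
        th, "sinusoid_thickness_mean", factor = "stage_region", pairs = fam)
  }
  out
}

write_provenance <- function(config, dir) {
  eff <- file.path(dir, "effective_config.yaml")
  yaml::write_yaml(config, eff)
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(eff)),
         seed = config$seed,
         package_version = as.character(packageVersion("fibromorph")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the full pipeline end to end
#'
#' Simulate (or load) a staged cohort, preprocess each volume, segment it (or
#' bypass segmentation with the generator's truth masks), quantify the
#' morphometry, and run the stage-comparison statistics. All outputs —
#' `results.csv` (one row per sample), `stats.csv`, `decision_trace.json`,
#' `effective_config.yaml`, `provenance.json` — are written once into
#' `out_dir`; rerunning with the same configuration reproduces them
#' bit-exactly.
#'
#' @param config nested configuration list (see [default_run_config()]), or
#'   a path to a YAML file.
#' @param out_dir output directory override; refuses to overwrite an
#'   existing `results.csv` unless `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty run directory.
#' @return Invisibly, a list with `results` (data frame), `stats` (list of
#'   `test_report`s) and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         overwrite = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(config$out_dir, "results.csv")
  if (file.exists(res_path) && !overwrite)
    stop("results.csv already exists in ", config$out_dir,
         "; outputs are write-once per run directory")

  cohort_def <- cohort_from_config(config)
  seg_cfg <- seg_config_from_config(config)
  results <- NULL
  stage_counter <- list()

  samples <- tryCatch(
    generate_cohort(cohort_def$schedule, cohort_def$template),
    error = function(e) stop("stage simulate: ", conditionMessage(e),
                             call. = FALSE))
  log_msg(config, "info", "simulated %d samples", length(samples))

  for (smp in samples) {
    sid <- sprintf("%s_r%02d", smp$label, smp$replicate)
    step <- "preprocess"
    row <- tryCatch({
      vol <- preprocess_volume(smp$volume,
                               factor = config$preprocess$factor,
                               percentile = config$preprocess$percentile)
      step <- "segment"
      masks <- if (isTRUE(config$segment$use_truth_masks)) smp$truth$masks
      else segment_volume(vol, seg_cfg)
      step <- "quantify"
      quantify_sample(masks, sample_id = sid)
    }, error = function(e)
      stop(sprintf("stage %s, sample %s: %s", step, sid,
                   conditionMessage(e)), call. = FALSE))
    row$label <- smp$label
    row$replicate <- smp$replicate
    results <- rbind(results, row)
    log_msg(config, "info", "quantified %s (lesion %.3f)", sid,
            row$lesion_volume_proportion)
  }

  write.csv(results, res_path, row.names = FALSE)

  tab <- morphometry_to_sample_table(results)
  stats <- cohort_stats(tab, alpha = config$stats$alpha,
                        control_stage = config$stats$control_stage)
  stats_df <- do.call(rbind, lapply(stats, as.data.frame))
  write.csv(stats_df, file.path(config$out_dir, "stats.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(stats, function(r) list(test = r$test, p = r$p,
                                   branch = r$branch, trace = r$trace)),
    file.path(config$out_dir, "decision_trace.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  write_provenance(config, config$out_dir)
  log_msg(config, "info", "pipeline complete: %s", config$out_dir)
  invisible(list(results = results, stats = stats,
                 out_dir = config$out_dir))
}
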