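# End-to-end orchestration: simulate -> quantify -> statistics -> report,
# with validated configuration and deterministic plain-file outputs.

pipeline_schema <- function() {
  list(
    stages = NULL,
    seed = NULL,
    write_images = NULL,
    ct_sim = names(formals(ct_sim_config)),
    texture = c("n_levels", "grey_limits", "hu_lo", "hu_hi", "band_depth",
                "n_bins_entropy"),
    histo_sim = setdiff(names(formals(histo_sim_config)), "vectors"),
    histo_quant = c("n_fields", "od_threshold", "size_range_um2",
                    "opening_radius_px"),
    qpcr = c("efficiency", "dilutions", "noise_sd", "intercept"),
    stats = c("variables", "transform"))
}

#' Validate a pipeline run configuration
#'
#' Checks every key (top-level and nested) against the known configuration
#' schema; unknown keys are rejected by name. Defaults are filled in for
#' anything omitted.
#'
#' @param config named list, or a path to a YAML/JSON config file.
#' @return The resolved configuration list (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  schema <- pipeline_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop("run_config: unknown configuration key(s): ",
         paste(bad, collapse = ", "))
  for (sec in names(schema)) {
    if (!is.null(schema[[sec]]) && !is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), schema[[sec]])
      if (length(bad))
        stop("run_config: unknown key(s) in '", sec, "': ",
             paste(bad, collapse = ", "))
    }
  }
  all_stages <- c("fixtures", "dose_summary", "simulate_ct", "ct_stats",
                  "ct_texture", "stats", "histo", "qpcr")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad))
    stop("run_config: unknown stage(s): ", paste(bad, collapse = ", "))
  config$seed <- config$seed %||% 1L
  config$write_images <- isTRUE(config$write_images)
  config$texture <- utils::modifyList(
    list(n_levels = 64, grey_limits = "auto", hu_lo = -1024, hu_hi = -242,
         band_depth = 10, n_bins_entropy = 256), config$texture %||% list())
  config$histo_quant <- utils::modifyList(
    list(n_fields = 6, od_threshold = 0.15, size_range_um2 = c(20, 500),
         opening_radius_px = 1), config$histo_quant %||% list())
  config$qpcr <- utils::modifyList(
    list(efficiency = 2, dilutions = 10^(0:-4), noise_sd = 0.05,
         intercept = 15), config$qpcr %||% list())
  config$stats <- utils::modifyList(
    list(variables = c("hu_mean", "hu_sd", "homogeneity"),
         transform = "none"), config$stats %||% list())
  config$ct_sim <- config$ct_sim %||% list()
  config$histo_sim <- config$histo_sim %||% list()
  class(config) <- "run_config"
  config
}

write_out <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' First-order and texture statistics for every slice/lung of a CT study
#'
#' Applies the subpleural-band first-order analysis and the masked GLCM
#' texture analysis to each (sheep, timepoint, lung) of a simulated or
#' loaded study, returning tidy long-format study tables.
#'
#' @param study list with `slices` and `masks` as from
#'   [simulate_ct_study()].
#' @param texture named list of texture/first-order parameters (see
#'   [run_config()]'s `texture` section).
#' @return List of two [study_table()]s: `first_order`, `texture`.
#' @export
ct_study_stats <- function(study, texture = run_config()$texture) {
  fo <- NULL; tx <- NULL
  for (sl in study$slices) {
    for (lung in names(study$masks)) {
      mask <- study$masks[[lung]]
      band <- suppressWarnings(subpleural_band(mask, texture$band_depth))
      f <- first_order_stats(sl, band)
      t <- ct_texture(sl, mask, texture$hu_lo, texture$hu_hi,
                      texture$n_levels, texture$grey_limits,
                      texture$n_bins_entropy)
      base <- data.frame(sheep_id = sl$sheep_id,
                         lung_label = mask$lung_label,
                         timepoint_days = sl$timepoint_days)
      fo_vars <- c("area_mm2", "hu_mean", "hu_sd", "hu_cv", "hu_min",
                   "hu_max", "skewness", "kurtosis_excess")
      tx_vars <- c("homogeneity", "contrast", "energy", "correlation",
                   "entropy_bits")
      fo <- rbind(fo, do.call(rbind, lapply(fo_vars, function(v)
        cbind(base, variable_name = v, value = f[[v]]))))
      tx <- rbind(tx, do.call(rbind, lapply(tx_vars, function(v)
        cbind(base, variable_name = v, value = t[[v]]))))
    }
  }
  list(first_order = study_table(fo), texture = study_table(tx))
}

#' Run the full pipeline into an output directory
#'
#' Executes the selected stages in dependency order and writes CSV results,
#' a JSON summary of every statistic with its parameters, the resolved
#' configuration, and a run log. Identical configuration and seed produce
#' byte-identical CSV/JSON outputs.
#'
#' @param config a [run_config()] (or list / config-file path coercible to
#'   one).
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the config's.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = run_config(), out_dir, seed = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  cfg_out <- config
  cfg_out$stages <- as.list(cfg_out$stages)
  jsonlite::write_json(unclass(cfg_out),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  summary <- list(seed = config$seed, stages = config$stages)

  if ("fixtures" %in% config$stages) {
    say("stage fixtures: writing bundled study tables")
    write_out(table1(), out_dir, "table1_plans")
    write_out(table3(), out_dir, "table3_first_order")
    write_out(table4(), out_dir, "table4_texture")
    write_out(table5(), out_dir, "table5_qpcr")
  }
  if ("dose_summary" %in% config$stages) {
    say("stage dose_summary: PTV fractions and goal checks")
    plans <- table1()
    cs <- cohort_summary(plans)
    goals <- check_planning_goals(plans)
    write_out(goals, out_dir, "planning_goals")
    write_out(data.frame(sheep_id = plans$sheep_id,
                         ptv_lung_fraction_pct = ptv_lung_fraction(plans)),
              out_dir, "ptv_lung_fraction")
    summary$dose_summary <- cs[c("mean_pct", "min_pct", "max_pct")]
  }
  if ("stats" %in% config$stages) {
    say("stage stats: paired-lung differences and RM-ANOVA on fixtures")
    d3 <- rx_con_difference(table3())
    d4 <- rx_con_difference(table4())
    write_out(d3, out_dir, "diffs_first_order")
    write_out(d4, out_dir, "diffs_texture")
    a_mean <- rm_anova(d3, "hu_mean", transform = config$stats$transform)
    a_hom <- rm_anova(d4, "homogeneity", transform = config$stats$transform)
    summary$fixture_rm_anova <- list(
      hu_mean = list(f = a_mean$f_value, p = a_mean$p_value,
                     df = a_mean$df,
                     transform = a_mean$transform_applied),
      homogeneity = list(f = a_hom$f_value, p = a_hom$p_value,
                         df = a_hom$df,
                         transform = a_hom$transform_applied))
  }
  study <- NULL
  if (any(c("simulate_ct", "ct_stats", "ct_texture") %in% config$stages)) {
    say("stage simulate_ct: generating phantom CT study")
    study <- simulate_ct_study(do.call(ct_sim_config, config$ct_sim),
                               seed = config$seed)
    write_out(study$truth, out_dir, "ct_truth")
    if (config$write_images) {
      img_dir <- file.path(out_dir, "ct_images")
      dir.create(img_dir, showWarnings = FALSE)
      for (sl in study$slices)
        write_ct_slice(sl, file.path(img_dir, paste0(sl$slice_id, ".tiff")))
    }
  }
  if (any(c("ct_stats", "ct_texture") %in% config$stages)) {
    say("stage ct_stats/ct_texture: masked first-order and GLCM statistics")
    res <- ct_study_stats(study, config$texture)
    write_out(res$first_order, out_dir, "ct_first_order")
    write_out(res$texture, out_dir, "ct_texture")
    if ("stats" %in% config$stages) {
      diffs <- rx_con_difference(rbind(res$first_order, res$texture))
      write_out(diffs, out_dir, "ct_diffs")
      anovas <- lapply(config$stats$variables, function(v) {
        a <- rm_anova(diffs, v, transform = config$stats$transform)
        list(variable = v, f = a$f_value, p = a$p_value,
             transform = a$transform_applied)
      })
      summary$ct_rm_anova <- anovas
    }
  }
  if ("histo" %in% config$stages) {
    say("stage histo: simulating and quantifying ", config$histo_quant$n_fields,
        " fields")
    hcfg <- do.call(histo_sim_config, config$histo_sim)
    rows <- NULL
    for (k in seq_len(config$histo_quant$n_fields)) {
      sim <- simulate_histology_field(hcfg, seed = config$seed + k)
      qa <- quantify_field(sim$field, hcfg$vectors, stain_channel = 1,
                           mode = "area",
                           od_threshold = config$histo_quant$od_threshold)
      qc <- quantify_field(sim$field, hcfg$vectors, stain_channel = 2,
                           mode = "count",
                           od_threshold = config$histo_quant$od_threshold,
                           size_range_um2 = config$histo_quant$size_range_um2,
                           opening_radius_px =
                             config$histo_quant$opening_radius_px)
      rows <- rbind(rows, data.frame(
        field = k, true_fraction = sim$truth$stain_area_fraction,
        est_fraction = qa$stain_area_fraction,
        true_cells = sim$truth$n_cells, est_cells = qc$positive_cell_count,
        cells_per_mm2 = qc$cells_per_mm2))
    }
    write_out(rows, out_dir, "histo_quant")
    summary$histo <- list(
      mean_abs_fraction_error = mean(abs(rows$est_fraction -
                                           rows$true_fraction)),
      count_exact_rate = mean(rows$est_cells == rows$true_cells))
  }
  if ("qpcr" %in% config$stages) {
    say("stage qpcr: standard curve and relative quantification")
    q <- config$qpcr
    sim <- simulate_qpcr(q$efficiency, q$dilutions, q$noise_sd, q$intercept,
                         seed = config$seed)
    curve <- fit_standard_curve(sim$log10_dilution, sim$cq)
    write_out(sim, out_dir, "qpcr_dilution_series")
    summary$qpcr <- list(true_efficiency = q$efficiency,
                         fitted_efficiency = curve$efficiency,
                         slope = curve$slope, r_squared = curve$r_squared)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done")
  invisible(summary)
}
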