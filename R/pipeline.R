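# End-to-end orchestration: simulate -> filter -> (drift-correct) ->
# cluster -> morphometry -> compare, with one seed, per-stage counts and a
# deterministic run manifest.

.pipeline_one_group <- function(scenario, config, out_dir, tag,
                                correct_length = FALSE) {
  params <- do.call(scenario_preset, scenario)
  aggregates <- sample_aggregates(params)
  table <- simulate_localizations(aggregates, params)
  n_sim <- nrow(table)
  fiducials <- NULL
  if (params$n_fiducials >= 1L || params$drift_rate > 0) {
    drifted <- apply_drift_and_fiducials(table, params)
    table <- drifted$table
    fiducials <- drifted$fiducials
  }
  loc_path <- file.path(out_dir, paste0(tag, "_localizations.csv"))
  write_localizations(table, loc_path)
  filtered <- filter_localizations(table, config$min_signal,
                                   config$max_precision)
  if (!is.null(fiducials)) {
    corrected <- correct_drift(filtered, fiducials,
                               n_frames = params$n_frames)
    filtered <- corrected$table
  }
  labeling <- dbscan_cluster(filtered, config$eps, config$min_pts)
  morpho <- summarize_sample(filtered, labeling,
                             correct_length = correct_length)
  morpho_path <- file.path(out_dir, paste0(tag, "_morphometry.csv"))
  write_morphometry(morpho, morpho_path)
  list(morpho = morpho,
       counts = list(simulated = n_sim, written = nrow(table),
                     filtered = nrow(filtered),
                     clustered = sum(labeling$labels >= 0L),
                     clusters = morpho$summary$n_clusters),
       files = c(loc_path, morpho_path))
}

#' Run the analysis pipeline end to end
#'
#' Subcommands: `"simulate"` (scenario to localization CSV), `"analyze"`
#' (simulate, filter, optionally drift-correct, cluster, measure),
#' `"compare"` (analyze two scenarios and compare their length
#' distributions), `"influx"` (simulate and quantify a liposome influx
#' field), `"all"` (synonym for `"compare"`). Every run writes its artifacts
#' plus a deterministic JSON manifest into `out_dir`.
#'
#' @param subcommand one of `"simulate"`, `"analyze"`, `"compare"`,
#'   `"influx"`, `"all"`.
#' @param config an [analysis_config()]; its `seed` is used unless `seed`
#'   is given.
#' @param scenario named list of [scenario_preset()] arguments for the
#'   (first) group; must contain `name`.
#' @param scenario_b second group for `"compare"`/`"all"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding `config$seed`.
#' @param correct_length use precision-corrected lengths in morphometry.
#' @return The run manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(subcommand = c("simulate", "analyze", "compare",
                                        "influx", "all"),
                         config = analysis_config(), scenario = NULL,
                         scenario_b = NULL, out_dir = tempfile("aggremorph"),
                         seed = NULL, correct_length = FALSE) {
  subcommand <- match.arg(subcommand)
  if (subcommand == "all") subcommand <- "compare"
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  counts <- list()

  if (subcommand %in% c("simulate", "analyze", "compare")) {
    if (is.null(scenario) || is.null(scenario$name))
      stop("scenario must be a named list containing 'name'", call. = FALSE)
  }
  if (subcommand == "simulate") {
    params <- do.call(scenario_preset, scenario)
    table <- simulate_localizations(sample_aggregates(params), params)
    if (params$n_fiducials >= 1L || params$drift_rate > 0)
      table <- apply_drift_and_fiducials(table, params)$table
    path <- file.path(out_dir, "localizations.csv")
    write_localizations(table, path)
    files <- path
    counts$simulated <- nrow(table)
  } else if (subcommand == "analyze") {
    res <- .pipeline_one_group(scenario, config, out_dir, "sample",
                               correct_length)
    files <- res$files
    counts <- res$counts
  } else if (subcommand == "compare") {
    if (is.null(scenario_b) || is.null(scenario_b$name))
      stop("scenario_b must be a named list containing 'name'", call. = FALSE)
    res_a <- .pipeline_one_group(scenario, config, out_dir, "group_a",
                                 correct_length)
    res_b <- .pipeline_one_group(scenario_b, config, out_dir, "group_b",
                                 correct_length)
    cmp <- compare_groups(res_a$morpho$records$length,
                          res_b$morpho$records$length,
                          bin_width = config$hist_bin_width,
                          names = c(scenario$name, scenario_b$name))
    cmp_path <- file.path(out_dir, "comparison.json")
    write_comparison(cmp, cmp_path)
    files <- c(res_a$files, res_b$files, cmp_path)
    counts <- list(group_a = res_a$counts, group_b = res_b$counts,
                   ks_D = cmp$ks_D, ks_p = cmp$ks_p)
  } else if (subcommand == "influx") {
    sim <- simulate_influx_experiment()
    res <- analyze_influx_experiment(sim$stack_background, sim$stack_sample,
                                     sim$stack_ionomycin,
                                     pixel_size = config$pixel_size_dl)
    path <- file.path(out_dir, "influx.csv")
    utils::write.csv(res$spots, path, row.names = FALSE)
    files <- path
    counts <- list(matched = nrow(res$spots), invalid = res$n_invalid,
                   mean_influx_pct = res$mean_influx_pct)
  }

  manifest <- list(subcommand = subcommand, seed = seed,
                   config = unclass(config),
                   scenario = scenario, scenario_b = scenario_b,
                   counts = counts, files = basename(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  stopifnot(all(file.exists(files)))
  invisible(manifest)
}
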