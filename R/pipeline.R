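#' Pipeline configuration
#'
#' Bundles every stage's parameters with a single master seed. The master
#' seed fans out to per-stage child seeds through a stable integer hash, so
#' any stage can be re-run in isolation and reproduce its part of a full
#' run. A resolved copy of the configuration is written next to the outputs
#' of [run_race_pipeline()]; identical resolved configuration and seed give
#' byte-identical outputs.
#'
#' @param seed Master integer seed.
#' @param n_cells Cohort size (default 5321).
#' @param preset Composition preset name (`"red_sea_default"`) or an
#'   [composition_preset()] object.
#' @param noise Noise model parameter list (see [noise_model()]).
#' @param preprocess,classify,typing,pca,sorter Per-stage parameter lists;
#'   omitted entries take the stage defaults.
#' @param out_dir Output directory.
#' @param write_spectra Write the cohort and processed matrices as CSV
#'   (default TRUE; disable for large exploratory runs).
#' @return A list of class `race_pipeline_config`.
#' @export
race_pipeline_config <- function(seed = 1, n_cells = 5321,
                                 preset = "red_sea_default",
                                 noise = list(), preprocess = list(),
                                 classify = list(), typing = list(),
                                 pca = list(), sorter = list(),
                                 out_dir = "race_out", write_spectra = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_cells = as.integer(n_cells), preset = preset,
    noise = utils::modifyList(
      list(read_sigma = 0.02, shot_scale = 0.05, baseline_poly_degree = 3,
           baseline_amplitude = 0.3, cosmic_ray_rate = 0), noise),
    preprocess = utils::modifyList(
      list(lam = 1e5, p = 0.01, n_iter = 10, smooth_window = 0,
           smooth_order = 2, norm_method = "vector"), preprocess),
    classify = utils::modifyList(
      list(theta_f = 0.85, snr_min = 3, min_prominence_sigma = 5,
           carotenoid_min_matches = 3, phb_min_matches = 4,
           base_min_matches = 2), classify),
    typing = utils::modifyList(list(tol_cm1 = 2, linkage = "single"), typing),
    pca = utils::modifyList(
      list(enabled = TRUE, n_components = 5, exclude_fluorescent = TRUE,
           alpha = 0.5), pca),
    sorter = utils::modifyList(
      list(query = "label == 'carotenoid'", n_wells = 12, cells_per_well = 1,
           success_prob = 1, acquisition_time = 5, max_targets = 10), sorter),
    out_dir = out_dir, write_spectra = isTRUE(write_spectra))
  class(cfg) <- "race_pipeline_config"
  cfg
}

#' @param path YAML file with any subset of the configuration fields.
#' @rdname race_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(race_pipeline_config, raw)
}

# Stable child-seed derivation: keeps every stage's randomness independent
# of the others while remaining a pure function of (seed, stage).
derive_child_seed <- function(seed, stage) {
  stage_index <- match(stage, c("simulate", "session"))
  if (is.na(stage_index)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 1103 + stage_index * 7919) %% 2147483647)
}

#' Run the full SCRS phenotyping and sorting pipeline
#'
#' Executes simulate -> preprocess -> classify -> type -> PCA -> sort plan
#' -> session simulation under one configuration, writes every stage's
#' output into `config$out_dir` (cohort and processed CSVs, ground truth,
#' calls, types, PCA loading windows, sort plan, manifest, resolved
#' configuration, JSON + text report) and returns the summary report. The
#' report assembles the cohort headline numbers: cells analysed, the
#' fluorescent/distinguishable split, carotenoid count and fraction, PHB
#' count, carotenoid type count, axis-1 loading windows and session totals.
#'
#' @param config An [race_pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return The report, an object of class `race_report` (a list; also
#'   written as `report.json` and `report.txt`).
#' @export
run_race_pipeline <- function(config = race_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "race_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  preset <- if (inherits(config$preset, "scrs_preset")) config$preset
            else if (identical(config$preset, "red_sea_default"))
              preset_red_sea_default(config$n_cells)
            else stop("unknown preset: ", config$preset, call. = FALSE)
  nm <- do.call(noise_model, config$noise)
  set <- simulate_cohort(preset, nm, seed = derive_child_seed(config$seed,
                                                              "simulate"))
  if (config$write_spectra) write_cohort_csv(set, out("cohort.csv"))
  utils::write.table(set$meta[, c("cell_id", "label", "v1", "v2", "v3")],
                     out("ground_truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  processed <- do.call(preprocess_spectra, c(list(set), config$preprocess))
  ccfg <- do.call(classify_config, config$classify)
  calls <- classify_cohort(processed, ccfg)
  utils::write.table(calls$calls, out("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  trip <- carotenoid_triplets(calls)
  types <- cluster_types(trip, tol_cm1 = config$typing$tol_cm1,
                         linkage = config$typing$linkage)
  utils::write.table(merge(types$assignment, trip, by = "cell_id"),
                     out("types.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  windows <- NULL
  evr <- NULL
  if (isTRUE(config$pca$enabled) &&
      sum(!calls$calls$is_fluorescent) >= 2) {
    pca <- scrs_pca(processed, n_components = config$pca$n_components,
                    exclude_fluorescent = config$pca$exclude_fluorescent,
                    calls = calls)
    windows <- top_loading_windows(pca, 1, alpha = config$pca$alpha)
    evr <- pca$explained_variance_ratio
    utils::write.table(windows, out("pc1_loading_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  layout <- chip_layout(config$sorter$n_wells)
  # one chip holds few cells: plan the first max_targets matching cells
  sel <- calls$calls
  hit <- eval(parse(text = config$sorter$query), sel, baseenv()) %in% TRUE
  keep_ids <- utils::head(sort(sel$cell_id[hit]), config$sorter$max_targets)
  plan <- build_sort_plan(sel[sel$cell_id %in% keep_ids, , drop = FALSE],
                          query = config$sorter$query, layout = layout,
                          cells_per_well = config$sorter$cells_per_well)
  manifest <- simulate_session(plan,
                               seed = derive_child_seed(config$seed,
                                                        "session"),
                               success_prob = config$sorter$success_prob,
                               acquisition_time = config$sorter$acquisition_time)
  utils::write.table(plan$targets, out("sort_plan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest_tsv(manifest, out("manifest.tsv"))

  report <- list(
    seed = config$seed,
    preset = preset$name,
    n_analysed = calls$n,
    counts = as.list(calls$counts),
    fractions = as.list(round(calls$fractions, 6)),
    frac_fluorescent = unname(calls$fractions["fluorescent"]),
    frac_distinguishable = unname(1 - calls$fractions["fluorescent"]),
    n_carotenoid = unname(calls$counts["carotenoid"]),
    frac_carotenoid = unname(calls$fractions["carotenoid"]),
    accuracy_vs_ground_truth = calls$accuracy,
    n_carotenoid_types = types$n_types,
    pc1_explained_variance = if (!is.null(evr)) evr[1] else NA,
    pc1_loading_windows = if (!is.null(windows))
      windows[, c("lo", "hi", "peak_loading")] else NULL,
    sort = as.list(manifest$totals),
    negative_control_cells = unname(
      manifest$well_counts[layout$controls$well[
        layout$controls$role == "negative_control"][1]]))
  class(report) <- "race_report"
  yaml::write_yaml(unclass_config(config), out("config_resolved.yaml"))
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(utils::capture.output(print(report)), out("report.txt"))
  report
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  if (inherits(cfg$preset, "scrs_preset"))
    cfg$preset <- list(name = cfg$preset$name,
                       fractions = as.list(cfg$preset$fractions),
                       n_cells = cfg$preset$n_cells)
  cfg
}

#' @export
print.race_report <- function(x, ...) {
  cat("RACE pipeline report\n")
  cat(sprintf("  preset %s, seed %d\n", x$preset, x$seed))
  cat(sprintf("  cells analysed:        %d\n", x$n_analysed))
  cat(sprintf("  fluorescence-dominated: %d (%.1f%%)\n",
              x$counts$fluorescent, 100 * x$frac_fluorescent))
  cat(sprintf("  distinguishable SCRS:   %.1f%%\n",
              100 * x$frac_distinguishable))
  cat(sprintf("  carotenoid-containing:  %d (%.1f%%)\n",
              x$n_carotenoid, 100 * x$frac_carotenoid))
  cat(sprintf("  PHB-containing:         %d\n", x$counts$phb))
  if (!is.null(x$accuracy_vs_ground_truth) &&
      !is.na(x$accuracy_vs_ground_truth))
    cat(sprintf("  accuracy vs ground truth: %.2f%%\n",
                100 * x$accuracy_vs_ground_truth))
  cat(sprintf("  carotenoid types:       %d\n", x$n_carotenoid_types))
  if (!is.null(x$pc1_loading_windows) && nrow(x$pc1_loading_windows)) {
    cat("  PC1 loading windows (cm^-1):\n")
    for (i in seq_len(nrow(x$pc1_loading_windows)))
      cat(sprintf("    %g-%g (peak |loading| %.3f)\n",
                  x$pc1_loading_windows$lo[i], x$pc1_loading_windows$hi[i],
                  x$pc1_loading_windows$peak_loading[i]))
  }
  cat(sprintf("  sort session: %d attempted, %d collected; negative-control well cells: %d\n",
              x$sort$attempted, x$sort$collected, x$negative_control_cells))
  invisible(x)
}
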