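#' Pipeline configuration
#'
#' Binds all stage configurations together. Input is either a
#' [scene_config()] to simulate, or a directory written by [write_scene()].
#'
#' @param scene a [scene_config()], or `NULL` when reading from `input_dir`.
#' @param input_dir directory with a scene (ignored when `scene` is given).
#' @param preprocess a [preprocess_config()].
#' @param fpd_rf [rf_config()] of the single-date binary forest
#'   (default 300 trees, 5 variables per split).
#' @param final_rf [rf_config()] of the three-class forest
#'   (default 300 trees, 10 variables per split).
#' @param post a [postprocess_config()].
#' @param reference_doys day(s) of year of the cloud-free reference
#'   acquisitions used to train the binary classifier.
#' @param max_train_px cap on training pixels per field (seeded).
#' @param hex_area_ha hexagon area for the QC aggregation, in hectares.
#' @param r2_threshold,p_threshold hotspot-flagging thresholds.
#' @param out_dir optional output directory; when given, all artifacts and
#'   the run manifest are written there.
#' @param seed master seed for the sampling steps.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL, input_dir = NULL,
                            preprocess = preprocess_config(),
                            fpd_rf = rf_config(300, 5, seed = 11),
                            final_rf = rf_config(300, 10, seed = 12),
                            post = postprocess_config(),
                            reference_doys = c(85, 120),
                            max_train_px = 60,
                            hex_area_ha = 9,
                            r2_threshold = 0.3, p_threshold = 1e-4,
                            out_dir = NULL, seed = 1) {
  if (is.null(scene) && is.null(input_dir)) {
    abort("either `scene` or `input_dir` is required",
          class = "plasticmapr_config_error")
  }
  if (!is.null(input_dir) && is.null(scene) && !dir.exists(input_dir)) {
    abort(sprintf("input_dir does not exist: %s", input_dir),
          class = "plasticmapr_config_error")
  }
  structure(list(scene = scene, input_dir = input_dir,
                 preprocess = preprocess, fpd_rf = fpd_rf,
                 final_rf = final_rf, post = post,
                 reference_doys = as.integer(reference_doys),
                 max_train_px = max_train_px, hex_area_ha = hex_area_ha,
                 r2_threshold = r2_threshold, p_threshold = p_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default end-to-end synthetic configuration
#'
#' The study conditions of the synthetic fixture: the default field layout
#' (20 fields per class plus a confounder block), 24 optical and 36 radar
#' dates, 30% mean cloud cover, 5-look speckle, and the default stage
#' configurations.
#'
#' @param seed master seed driving the scene and every sampling step.
#' @return a [pipeline_config()].
#' @export
default_pipeline_config <- function(seed = 42) {
  pipeline_config(
    scene = scene_config(
      field_layout = default_field_layout(seed = seed),
      seed = seed
    ),
    fpd_rf = rf_config(300, 5, seed = seed + 1L),
    final_rf = rf_config(300, 10, seed = seed + 2L),
    seed = seed
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline failed in stage \"%s\": %s", name,
                  conditionMessage(e)),
          class = "plasticmapr_stage_error", parent = e)
  })
}

#' Run the full mapping pipeline
#'
#' Executes simulate/read, preprocessing, both feature-extraction branches,
#' classification, sieving, accuracy assessment and spatial QC in order.
#' Rerunning with the same configuration (and seeds) reproduces bit-identical
#' class maps and reports.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `plastic_run`: list with the scene, fused
#'   series, feature stack components, raw and sieved class maps, accuracy
#'   reports (three-class, binary, field-size sweep), QC tables, the feature
#'   importance and a run `manifest`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  scene <- stage("simulate", {
    if (!is.null(config$scene)) generate_scene(config$scene)
    else read_raster_series(config$input_dir)
  })
  ps <- scene$truth$pixel_size

  fused <- stage("preprocess", {
    preprocess_series(scene$optical, scene$radar,
                      config = config$preprocess, pixel_size = ps)
  })

  features <- stage("features", {
    if (is.null(scene$fields) || !nrow(scene$fields)) {
      abort("no labelled fields available for training")
    }
    agg <- aggregate_annual(fused, min_obs = config$preprocess$min_obs)
    train_fields <- dplyr::filter(scene$fields, .data$role == "train")
    ref <- purrr::keep(fused$acquisitions,
                       ~ .x$doy %in% config$reference_doys)
    if (!length(ref)) {
      abort("no fused acquisition at the configured reference day(s)")
    }
    binary_fields <- dplyr::mutate(
      train_fields, label_bin = ifelse(.data$truth_class == "PFF", 0L, 1L))
    bin_samples <- dplyr::bind_rows(lapply(ref, function(a) {
      extract_samples(a, binary_fields, label_field = "label_bin",
                      max_per_field = config$max_train_px,
                      seed = config$seed)
    }))
    bin_clf <- train_binary_classifier(bin_samples,
                                       n_trees = config$fpd_rf$n_trees,
                                       vars_per_split = config$fpd_rf$vars_per_split,
                                       seed = config$fpd_rf$seed)
    fpd <- compute_fpd(fused, bin_clf)
    stack <- build_feature_stack(agg, fpd)
    list(agg = agg, fpd = fpd, stack = stack, bin_clf = bin_clf,
         train_fields = train_fields)
  })

  cls <- stage("classify", {
    samples <- extract_samples(features$stack, features$train_fields,
                               label_field = "truth_class",
                               max_per_field = config$max_train_px,
                               seed = config$seed + 1L)
    clf <- train_final_classifier(samples, rf = config$final_rf)
    mask <- !is.na(scene$truth$codes)  # the cropland-mask analogue
    map_raw <- predict_map(features$stack, clf, mask)
    map <- sieve(map_raw, config$post)
    list(clf = clf, map_raw = map_raw, map = map,
         importance = feature_importance(clf))
  })

  evaluation <- stage("evaluate", {
    validation <- scene$fields |>
      dplyr::filter(.data$role == "validation") |>
      dplyr::mutate(label_2020 = .data$truth_class,
                    label_binary = merge_to_binary(.data$truth_class))
    if (!nrow(validation)) {
      NULL
    } else {
      cm3 <- confusion_matrix(cls$map, validation, "label_2020",
                              classes = plastic_classes())
      binary_map <- class_map(
        matrix(match(merge_to_binary(as.vector(class_map_labels(cls$map))),
                     c("PFF", "plastic-covered")),
               nrow(cls$map$codes), ncol(cls$map$codes)),
        levels = c("PFF", "plastic-covered"), pixel_size = ps)
      cm2 <- confusion_matrix(binary_map, validation, "label_binary",
                              classes = c("PFF", "plastic-covered"))
      list(validation = validation,
           confusion_3class = cm3, report_3class = accuracy_metrics(cm3),
           confusion_binary = cm2, report_binary = accuracy_metrics(cm2),
           sweep = field_size_sweep(cls$map, validation))
    }
  })

  qc <- stage("qc", {
    extent <- c(0, ncol(scene$truth$codes) * ps,
                0, nrow(scene$truth$codes) * ps)
    grid <- build_hex_grid(extent, config$hex_area_ha)
    sc <- soil_cover(fused)
    areas <- hex_aggregate_area(cls$map, grid)
    reg <- hex_regression(features$fpd, sc, grid)
    flags <- flag_hotspots(reg, config$r2_threshold, config$p_threshold)
    list(grid = grid, soil_cover = sc, areas = areas, regression = reg,
         flags = flags)
  })

  manifest <- list(
    config = config,
    n_optical_in = length(scene$optical),
    n_radar_in = length(scene$radar),
    dropped_cloudy_doys = attr(fused, "dropped_doys"),
    n_fused = length(fused),
    pairing = attr(fused, "pairing"),
    sieve_removed = attr(cls$map, "n_removed"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  run <- structure(
    list(scene = scene, fused = fused, agg = features$agg,
         fpd = features$fpd, stack = features$stack,
         binary_classifier = features$bin_clf, classifier = cls$clf,
         map_raw = cls$map_raw, map = cls$map,
         importance = cls$importance, evaluation = evaluation, qc = qc,
         manifest = manifest),
    class = "plastic_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.plastic_run <- function(x, ...) {
  cat("<plastic_run>\n")
  cat(sprintf("  fused acquisitions: %d (dropped cloudy: %d)\n",
              length(x$fused),
              length(x$manifest$dropped_cloudy_doys %||% integer(0))))
  print(x$map)
  if (!is.null(x$evaluation)) {
    cat(sprintf("  3-class OA %.1f%% | binary OA %.1f%%\n",
                round_half_up(100 * x$evaluation$report_3class$overall, 1),
                round_half_up(100 * x$evaluation$report_binary$overall, 1)))
  }
  invisible(x)
}

#' Write the artifacts of a pipeline run
#'
#' Class maps, FPD, soil-cover, accuracy tables, QC tables, hexagon GeoJSON
#' and the JSON run manifest.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- run$map$pixel_size
  write_class_map(run$map, file.path(dir, "class_map.asc"))
  write_class_map(run$map_raw, file.path(dir, "class_map_raw.asc"))
  write_asc(run$fpd$fpd, file.path(dir, "fpd.asc"), cellsize = ps)
  write_asc(run$qc$soil_cover$soil_cover, file.path(dir, "soil_cover.asc"),
            cellsize = ps)
  utils::write.csv(run$importance, file.path(dir, "feature_importance.csv"),
                   row.names = FALSE)
  if (!is.null(run$evaluation)) {
    utils::write.csv(tidy(run$evaluation$report_3class),
                     file.path(dir, "accuracy_3class.csv"), row.names = FALSE)
    utils::write.csv(tidy(run$evaluation$report_binary),
                     file.path(dir, "accuracy_binary.csv"), row.names = FALSE)
    utils::write.csv(run$evaluation$sweep,
                     file.path(dir, "field_size_sweep.csv"), row.names = FALSE)
  }
  utils::write.csv(dplyr::select(run$qc$flags, -dplyr::any_of("vertices")),
                   file.path(dir, "hex_qc.csv"), row.names = FALSE)
  write_hex_geojson(run$qc$grid,
                    dplyr::left_join(run$qc$flags, run$qc$areas,
                                     by = c("hex_id", "cx", "cy")),
                    file.path(dir, "hex_qc.geojson"))
  manifest <- run$manifest
  jsonlite::write_json(
    list(elapsed_s = manifest$elapsed_s,
         n_optical_in = manifest$n_optical_in,
         n_radar_in = manifest$n_radar_in,
         n_fused = manifest$n_fused,
         dropped_cloudy_doys = manifest$dropped_cloudy_doys,
         sieve_removed = manifest$sieve_removed,
         seeds = list(master = run$manifest$config$seed,
                      fpd_rf = run$manifest$config$fpd_rf$seed,
                      final_rf = run$manifest$config$final_rf$seed)),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
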