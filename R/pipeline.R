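# Configuration and end-to-end orchestration: simulate/ingest -> clean/thin ->
# background -> fit -> cross-validate -> gate/ensemble -> interpret ->
# project -> report. One master seed; every stage draws from a seed derived
# by hashing the stage name, so adding a stage never perturbs the randomness
# of earlier stages.

#' Default pipeline configuration
#'
#' The synthetic study conditions: a 100 x 100 grid at 0.1 degrees with a
#' meandering east coast, a strong-signal virtual species (thermal plus
#' precipitation niche), 300 presence records, the 1:2
#' presence:pseudo-absence design on the full domain, 500-tree forest,
#' 10-knot features, stratified 5-fold CV, gates AUC >= 0.90 / TSS >= 0.70,
#' P10 plus fixed thresholds {0.3, 0.5, 0.7}, and low/high warming scenarios
#' for two horizons.
#'
#' @param seed Master seed.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(lon_min = 100, lon_max = 110, lat_min = 20, lat_max = 30,
                resolution = 0.1),
    simulate = list(
      correlation_length = 6,
      ocean_fraction = 0.2,
      n_presences = 300,
      species_name = "virtual_inland_taxon",
      combination = "product",
      responses = list(
        BIO1 = list(type = "gaussian", opt = 18, breadth = 1.8),
        BIO12 = list(type = "gaussian", opt = 1500, breadth = 300))),
    occurrences = list(year_range = c(2014L, 2024L), thin_km = 1),
    background = list(type = "full-domain", buffer_km = 200, ratio = 2),
    model = list(n_trees = 500, n_knots = 10,
                 classes = c("linear", "quadratic", "product", "hinge")),
    cv = list(k = 5),
    gates = list(auc_min = 0.90, tss_min = 0.70),
    thresholds = c(0.3, 0.5, 0.7),
    scenarios = list(
      list(name = "ssp_low", horizon = "2030s", temp_offset = 1.0,
           precip_scale = 1.03, landuse_trend = c(Urban = 2, Crop = -2)),
      list(name = "ssp_low", horizon = "2050s", temp_offset = 1.8,
           precip_scale = 1.05, landuse_trend = c(Urban = 3, Crop = -4)),
      list(name = "ssp_high", horizon = "2030s", temp_offset = 1.5,
           precip_scale = 1.02, landuse_trend = c(Urban = 4, Crop = 2)),
      list(name = "ssp_high", horizon = "2050s", temp_offset = 3.0,
           precip_scale = 1.04, landuse_trend = c(Urban = 6, Crop = 4))),
    interpret = list(n_reps = 10, shap_points = 40, shap_background = 40,
                     pdp_grid = 20))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

stage_seed <- function(config, stage) derive_seed(config$seed, stage)

#' Run the full modelling pipeline
#'
#' Executes every stage on either synthetic inputs (default) or user data
#' (`config$input` with an occurrence CSV and named GeoTIFF layer paths),
#' writes the tabular and raster artifacts plus a run manifest (stage seeds,
#' row counts, md5 content hashes) under `output_dir`, and returns the
#' fitted objects. Fails fast with stage-named errors.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param output_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return Invisible list: `stack`, `species` (synthetic runs), `presences`,
#'   `training`, `cv`, `ensemble`, `interpretation`, `scenarios`,
#'   `summary_table`, `area_table`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), output_dir = NULL) {
  at_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", stage, "]: ", conditionMessage(e), call. = FALSE))
  }
  log_counts <- list()

  ## ingest or simulate ------------------------------------------------------
  grid <- at_stage("grid", do.call(make_grid, config$grid))
  species <- NULL
  if (!is.null(config$input)) {
    stack <- at_stage("ingest", read_stack(unlist(config$input$layers)))
    coast <- if (!is.null(config$input$coast))
      at_stage("ingest", read_geotiff(config$input$coast)) else NULL
    occ_raw <- at_stage("ingest",
      utils::read.csv(config$input$occurrences, stringsAsFactors = FALSE))
    grid <- stack$grid
  } else {
    coast <- at_stage("simulate",
      simulate_coastline(grid, seed = stage_seed(config, "coast"),
                         ocean_fraction = config$simulate$ocean_fraction))
    stack <- at_stage("simulate",
      simulate_predictor_stack(grid, config$simulate$correlation_length,
                               seed = stage_seed(config, "stack"), land = coast))
    species <- at_stage("simulate",
      make_virtual_species(stack, config$simulate$responses,
                           combination = config$simulate$combination))
    occ_raw <- at_stage("simulate",
      sample_presences(species, config$simulate$n_presences,
                       seed = stage_seed(config, "presences"),
                       name = config$simulate$species_name))
  }
  log_counts$raw_records <- nrow(occ_raw)

  ## occurrences -------------------------------------------------------------
  occ <- at_stage("clean",
    clean_occurrences(occ_raw, grid, config$occurrences$year_range, land = coast))
  occ <- at_stage("thin", thin_occurrences(occ, config$occurrences$thin_km))
  presence_cells <- at_stage("aggregate",
    aggregate_to_grid(occ, grid, stack$valid))
  log_counts$clean_records <- nrow(occ)
  log_counts$presence_cells <- length(presence_cells)

  ## background --------------------------------------------------------------
  buffer <- NULL
  if (config$background$type == "coastal-buffer") {
    if (is.null(coast)) stop("pipeline stage [background]: coastal-buffer needs a coast raster")
    buffer <- at_stage("background",
      coastal_buffer_mask(grid, coast, config$background$buffer_km))
  }
  pa_cells <- at_stage("background",
    sample_pseudo_absences(stack$valid, presence_cells,
                           ratio = config$background$ratio,
                           background = config$background$type,
                           buffer = buffer,
                           seed = stage_seed(config, "background")))
  train <- at_stage("training-table",
    build_training_table(presence_cells, pa_cells, stack))
  log_counts$pseudo_absences <- length(pa_cells)
  log_counts$training_rows <- nrow(train)

  ## fit + cross-validate ----------------------------------------------------
  fspec <- feature_spec(config$model$classes, config$model$n_knots)
  fit_mx <- function(tr, seed) fit_maxent(tr, fspec, seed = seed)
  fit_rf <- function(tr, seed) fit_forest(tr, n_trees = config$model$n_trees,
                                          seed = seed)
  cv_mx <- at_stage("cv", cross_validate(fit_mx, train, k = config$cv$k,
    seed = stage_seed(config, "cv-maxent"), algorithm = "maxent-style"))
  cv_rf <- at_stage("cv", cross_validate(fit_rf, train, k = config$cv$k,
    seed = stage_seed(config, "cv-forest"), algorithm = "forest"))
  mx <- at_stage("fit", fit_mx(train, stage_seed(config, "fit-maxent")))
  rf <- at_stage("fit", fit_rf(train, stage_seed(config, "fit-forest")))

  ## ensemble ----------------------------------------------------------------
  ens <- at_stage("ensemble",
    build_ensemble(list(mx, rf), list(cv_mx, cv_rf), stack, presence_cells,
                   auc_min = config$gates$auc_min,
                   tss_min = config$gates$tss_min))

  ## interpret ---------------------------------------------------------------
  icfg <- config$interpret
  interp <- at_stage("interpret", {
    set.seed(stage_seed(config, "interpret-sample"))
    ev <- train[sample(nrow(train), min(icfg$shap_points, nrow(train))), ]
    bg <- train[sample(nrow(train), min(icfg$shap_background, nrow(train))), ]
    shap <- shap_values(ens, bg, ev)
    mabs <- mean_abs_shap(shap)
    list(
      collinearity = collinearity_screen(train[, ens$predictors]),
      importance = permutation_importance(ens, train, n_reps = icfg$n_reps,
                                          seed = stage_seed(config, "perm")),
      shap = shap,
      shap_summary = data.frame(predictor = names(mabs),
                                mean_abs_shap = unname(mabs),
                                effect = classify_shap(unname(mabs))),
      pdp = lapply(stats::setNames(nm = ens$predictors), partial_dependence,
                   model = ens, reference = train, n_grid = icfg$pdp_grid))
  })

  ## project -----------------------------------------------------------------
  areas <- cell_area_raster(grid)
  baseline_binary <- binarize(ens$surface, ens$p10)
  scen_results <- lapply(config$scenarios, function(sc) at_stage(
    paste0("project:", sc$name, ":", sc$horizon), {
      spec <- scenario_spec(sc$name, sc$temp_offset, sc$precip_scale,
                            unlist(sc$landuse_trend), sc$horizon)
      res <- project_scenario(ens, perturb_scenario(stack, spec),
                              label = paste(sc$name, sc$horizon),
                              thresholds = config$thresholds)
      res$change <- change_map(baseline_binary, res$binary)
      res
    }))

  ## report ------------------------------------------------------------------
  base_summary <- suitability_summary(ens$surface)
  base_fixed <- area_above_thresholds(ens$surface, config$thresholds, areas)
  summary_table <- rbind(
    data.frame(scenario = "baseline", t(base_summary)),
    do.call(rbind, lapply(scen_results, function(r)
      data.frame(scenario = r$label, t(r$summary)))))
  area_table <- rbind(
    data.frame(scenario = "baseline", t(base_fixed),
               p10_area_km2 = ens$baseline_area_km2, delta_km2 = 0,
               check.names = FALSE),
    do.call(rbind, lapply(scen_results, function(r)
      data.frame(scenario = r$label, t(r$fixed_areas),
                 p10_area_km2 = r$p10_area_km2, delta_km2 = r$delta_km2,
                 check.names = FALSE))))

  manifest <- list(
    package = "ensdm",
    version = as.character(utils::packageVersion("ensdm")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(c("coast", "stack", "presences", "background", "cv-maxent",
               "cv-forest", "fit-maxent", "fit-forest", "interpret-sample",
               "perm"), stage_seed, config = config),
      c("coast", "stack", "presences", "background", "cv-maxent", "cv-forest",
        "fit-maxent", "fit-forest", "interpret-sample", "perm")),
    counts = log_counts,
    gates = config$gates,
    weights = as.numeric(ens$weights),
    p10 = ens$p10,
    config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    wcsv <- function(df, name) {
      p <- file.path(output_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      paths[[name]] <<- p
    }
    wcsv(cv_metrics_table(cv_mx, cv_rf), "cv_metrics.csv")
    wcsv(summary_table, "suitability_summary.csv")
    wcsv(area_table, "suitable_area.csv")
    wcsv(interp$importance, "permutation_importance.csv")
    wcsv(interp$shap_summary, "shap_summary.csv")
    wcsv(do.call(rbind, lapply(names(interp$pdp), function(nm)
      cbind(predictor = nm, interp$pdp[[nm]]))), "partial_dependence.csv")
    wtif <- function(r, name) {
      p <- file.path(output_dir, name)
      write_geotiff(r, p)
      paths[[name]] <<- p
    }
    wtif(ens$surface, "suitability_baseline.tif")
    wtif(baseline_binary, "binary_baseline.tif")
    for (r in scen_results) {
      slug <- gsub("[^a-z0-9]+", "_", tolower(r$label))
      wtif(r$surface, paste0("suitability_", slug, ".tif"))
      wtif(r$binary, paste0("binary_", slug, ".tif"))
      wtif(r$change, paste0("change_", slug, ".tif"))
    }
    p <- file.path(output_dir, "ensemble.txt")
    write_ensemble_description(ens, p)
    paths[["ensemble.txt"]] <- p
    manifest$outputs <- as.list(unname(Map(function(nm, p)
      list(file = nm, md5 = unname(tools::md5sum(p))), names(paths), paths)))
    manifest_path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  invisible(list(grid = grid, stack = stack, coast = coast, species = species,
                 presences = occ, presence_cells = presence_cells,
                 pseudo_absence_cells = pa_cells, training = train,
                 cv = list(maxent = cv_mx, forest = cv_rf),
                 models = list(maxent = mx, forest = rf),
                 ensemble = ens, interpretation = interp,
                 scenarios = scen_results,
                 summary_table = summary_table, area_table = area_table,
                 manifest = manifest))
}
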