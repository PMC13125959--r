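# Scenario projection, continuous-suitability summaries, threshold areas and
# net-change accounting.

#' Summary statistics of a suitability surface
#'
#' Mean, median and 95th percentile over valid cells, the quantiles using
#' linear interpolation between order statistics (the default `type = 7`
#' convention; the P10 threshold uses the coverage-preserving `type = 6`
#' variant instead, see [p10_threshold()]).
#'
#' @param surface An `sdm_raster`.
#' @return Named numeric vector `mean`, `median`, `p95`.
#' @export
suitability_summary <- function(surface) {
  v <- surface$values[!is.na(surface$values)]
  if (!length(v)) stop("surface has no valid cells")
  c(mean = mean(v),
    median = unname(stats::quantile(v, 0.5, type = 7)),
    p95 = unname(stats::quantile(v, 0.95, type = 7)))
}

#' Suitable area above fixed thresholds
#'
#' @param surface An `sdm_raster` in \[0, 1\].
#' @param thresholds Sorted thresholds (default `c(0.3, 0.5, 0.7)`).
#' @param areas Cell-area raster (defaults to [cell_area_raster()] of the
#'   surface grid).
#' @return Named vector of km^2 with suitability >= each threshold
#'   (non-increasing in the threshold).
#' @export
area_above_thresholds <- function(surface, thresholds = c(0.3, 0.5, 0.7),
                                  areas = NULL) {
  if (is.null(areas)) areas <- cell_area_raster(surface$grid)
  vapply(stats::setNames(thresholds, paste0("area_", thresholds)),
         function(th) suitable_area(binarize(surface, th), areas), numeric(1))
}

#' Net change in suitable area
#'
#' `scenario - baseline` in km^2; negative values are net losses.
#'
#' @param baseline_km2,scenario_km2 Non-negative areas.
#' @return Signed delta in km^2.
#' @export
area_change <- function(baseline_km2, scenario_km2) {
  if (any(baseline_km2 < 0) || any(scenario_km2 < 0)) stop("areas must be >= 0")
  scenario_km2 - baseline_km2
}

#' Project an ensemble onto a scenario stack
#'
#' Produces the continuous scenario surface, the binary surface via the
#' baseline-derived ensemble P10 (default; set `p10 = "recompute"` to
#' re-derive P10 from scenario suitability at the calibration presences),
#' the mean/median/95th-percentile summary, areas above fixed thresholds,
#' the P10 area, and the net change against the ensemble baseline area.
#'
#' @param ensemble An `ensemble_sdm` from [build_ensemble()].
#' @param scenario_stack A `predictor_stack` with the training layers.
#' @param label Scenario label.
#' @param thresholds Fixed suitability thresholds for area accounting.
#' @param p10 `"baseline"` (default) or `"recompute"`.
#' @return A `scenario_result`: `label`, `surface`, `binary`, `summary`,
#'   `fixed_areas`, `p10_used`, `p10_area_km2`, `delta_km2`.
#' @export
project_scenario <- function(ensemble, scenario_stack, label = "scenario",
                             thresholds = c(0.3, 0.5, 0.7),
                             p10 = c("baseline", "recompute")) {
  p10 <- match.arg(p10)
  surface <- predict_surface(ensemble, scenario_stack)
  thr <- if (p10 == "baseline") ensemble$p10 else
    p10_threshold(as.vector(t(surface$values))[ensemble$presence_cells])
  areas <- cell_area_raster(scenario_stack$grid)
  binary <- binarize(surface, thr)
  p10_area <- suitable_area(binary, areas)
  structure(list(label = label, surface = surface, binary = binary,
                 summary = suitability_summary(surface),
                 fixed_areas = area_above_thresholds(surface, thresholds, areas),
                 p10_used = thr, p10_area_km2 = p10_area,
                 delta_km2 = area_change(ensemble$baseline_area_km2, p10_area)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: mean %.3f median %.3f p95 %.3f; P10 area %.0f km^2 (delta %.0f)\n",
              x$label, x$summary["mean"], x$summary["median"], x$summary["p95"],
              x$p10_area_km2, x$delta_km2))
  invisible(x)
}

#' Categorical change map between two binary surfaces
#'
#' Cellwise 2x2 classification: 0 stable-unsuitable, 1 loss (1 -> 0),
#' 2 gain (0 -> 1), 3 stable-suitable. By construction
#' `area(gain) - area(loss)` equals the net area change between the two
#' binary maps.
#'
#' @param binary_baseline,binary_scenario `sdm_raster`s in {0, 1} on one grid.
#' @return An `sdm_raster` with attribute `legend`.
#' @export
change_map <- function(binary_baseline, binary_scenario) {
  if (!grid_equal(binary_baseline$grid, binary_scenario$grid))
    stop("grid mismatch")
  b <- binary_baseline$values; s <- binary_scenario$values
  v <- b + 2 * s   # 0 stable-unsuitable, 1 loss, 2 gain, 3 stable-suitable
  out <- sdm_raster(binary_baseline$grid, v)
  attr(out, "legend") <- c(`0` = "stable-unsuitable", `1` = "loss",
                           `2` = "gain", `3` = "stable-suitable")
  out
}

#' Area of each change-map category
#' @param cmap Raster from [change_map()].
#' @param areas Cell-area raster (defaults to the grid's).
#' @return Named vector of km^2 for loss, gain, stable categories.
#' @export
change_map_areas <- function(cmap, areas = NULL) {
  if (is.null(areas)) areas <- cell_area_raster(cmap$grid)
  v <- cmap$values
  vapply(c(stable_unsuitable = 0, loss = 1, gain = 2, stable_suitable = 3),
         function(code) sum(areas$values[!is.na(v) & v == code]), numeric(1))
}
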